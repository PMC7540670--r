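# Scoring rule, quadrature deviance, expert score and its decomposition.

test_that("occupancy probability follows 1 - exp(-lambdaBar) with clamping", {
  g <- makeGrid(unitSquare(), 30)  # 4 cells
  s <- occupancyProbability(c(log(2), 0, 50, 1), g)
  p <- occupancy(s)
  expect_equal(p[1], 0.5)
  expect_equal(p[2], 1e-10)        # clamped up from 0
  expect_equal(p[3], 1 - 1e-10)    # clamped down from ~1
  expect_equal(p[4], 1 - exp(-1))
  expect_equal(s@nClamped, 2L)
  expect_error(occupancyProbability(c(-1, 0, 0, 0), g), "negative")
})

test_that("the scoring rule matches its closed forms and is non-negative", {
  expect_equal(scoringRule(1, 0.5), 2 * log(2))
  expect_equal(scoringRule(0, 0.75), -2 * log(0.25))
  expect_lt(scoringRule(1, 1 - 1e-10), 1e-9)
  expect_error(scoringRule(1, 1), "strictly inside")
  expect_error(scoringRule(2, 0.5), "0 or 1")
  set.seed(7)
  expect_true(all(scoringRule(rbinom(50, 1, 0.5), runif(50, 0.01, 0.99)) >= 0))
})

test_that("total deviance equals the brute-force quadrature sum", {
  g <- makeGrid(rectanglePolygon(0, 0, 1, 0.5), 15)  # 4 x 2 = 8 cells
  set.seed(11)
  lb <- runif(8, 0.05, 3)
  s <- occupancyProbability(lb, g)
  y <- rasterizeMap(rectanglePolygon(0, 0, 0.5, 0.5), g)
  m <- gridMask(g)
  oracle <- bruteDeviance(occupancy(y)[m], occupancy(s)[m], cellAreas(g)[m])
  expect_equal(totalDeviance(y, s), oracle, tolerance = 1e-12)
  # unit weights: closed form J * 2log2 when all p = 0.5
  s2 <- occupancyProbability(rep(log(2), 8), g)
  expect_equal(totalDeviance(y, s2, weights = 1), 8 * 2 * log(2),
    tolerance = 1e-12)
  # grid mismatch
  g2 <- makeGrid(rectanglePolygon(0, 0, 1, 0.5), 10)
  expect_error(totalDeviance(y, occupancyProbability(runif(18, 0.1, 1), g2)),
    "mismatch")
})

test_that("the null map scores exactly zero", {
  region <- rectanglePolygon(-100, 32, -96, 35)
  g <- makeGrid(region, 10)
  s <- randomSurface(g, seed = 21)
  res <- expertScore(region, s)
  expect_identical(res@expertScore, 0)
  expect_identical(res@scaledOutside, 0)
  expect_equal(res@scaledInside, 1)
})

test_that("expert score decomposes exactly into commission and omission", {
  for (seed in 1:25) {
    g <- makeGrid(rectanglePolygon(0, 0, 2, 1), 20)  # 6 x 3 cells
    s <- randomSurface(g, seed)
    set.seed(seed + 1000)
    y <- new("BinaryMapGrid", y = rbinom(18, 1, 0.5), grid = g)
    res <- expertScore(y, s)
    expect_equal(res@devianceExpert, res@devianceInside + res@devianceOutside,
      tolerance = 1e-12)
    expect_equal(res@expertScore, 1 - (res@scaledInside + res@scaledOutside),
      tolerance = 1e-12)
    m <- gridMask(g)
    oracle <- bruteExpertScore(occupancy(y)[m], occupancy(s)[m], cellAreas(g)[m])
    expect_equal(res@expertScore, oracle$score, tolerance = 1e-12)
  }
})

test_that("a map matching the suitable half scores near 1, the wrong half below 0", {
  region <- rectanglePolygon(0, 0, 1, 0.5)
  g <- makeGrid(region, 30)   # 2 x 1 cells
  s <- occupancyProbability(c(50, 0), g)   # p ~ 1 and p ~ 0
  high <- rectanglePolygon(0, 0, 0.5, 0.5)
  low <- rectanglePolygon(0.5, 0, 1, 0.5)
  expect_gt(expertScore(high, s)@expertScore, 0.99)
  # brute-force two-cell oracle for the wrong-half map
  m <- gridMask(g)
  oracle <- bruteExpertScore(c(0, 1), occupancy(s)[m], cellAreas(g)[m])
  resLow <- expertScore(low, s)
  expect_equal(resLow@expertScore, oracle$score, tolerance = 1e-12)
  expect_lt(resLow@expertScore, 0)
})

test_that("adding suitable cells helps, unsuitable cells hurt", {
  g <- makeGrid(rectanglePolygon(0, 0, 2, 1), 20)
  s <- randomSurface(g, seed = 31)
  p <- occupancy(s)
  set.seed(32)
  y0 <- rbinom(18, 1, 0.5)
  base <- expertScore(new("BinaryMapGrid", y = y0, grid = g), s)@expertScore
  for (j in which(y0 == 0)) {
    y1 <- y0; y1[j] <- 1L
    delta <- expertScore(new("BinaryMapGrid", y = y1, grid = g), s)@expertScore - base
    if (p[j] > 0.5) expect_gte(delta, 0) else expect_lte(delta, 0)
  }
})

test_that("the score is invariant to uniform weight rescaling", {
  g <- makeGrid(rectanglePolygon(0, 0, 2, 1), 20)
  s <- randomSurface(g, seed = 41)
  y <- rasterizeMap(rectanglePolygon(0, 0, 1, 1), g)
  r1 <- expertScore(y, s)
  r2 <- expertScore(y, s, weights = cellAreas(g) * 137.5)
  expect_equal(r1@expertScore, r2@expertScore, tolerance = 1e-12)
  expect_equal(r1@scaledInside, r2@scaledInside, tolerance = 1e-12)
  expect_equal(r1@scaledOutside, r2@scaledOutside, tolerance = 1e-12)
})

test_that("degenerate all-certain surfaces are rejected", {
  g <- makeGrid(unitSquare(), 30)
  s <- occupancyProbability(rep(60, 4), g)   # every p at the upper clamp
  expect_error(expertScore(unitSquare(), s), "degenerate")
})

test_that("refining the grid moves the score less than the reported bound", {
  sc <- makeScenario(5)
  run10 <- scenarioScores(sc, resolutionArcmin = 10)
  g5 <- makeGrid(sc@region, 5)
  lam5 <- makeIntensity(sc, g5)
  s5 <- occupancyProbability(integrateIntensity(lam5, g5), g5)
  score5 <- expertScore(run10$tightMap, s5)@expertScore
  score10 <- run10$tight@expertScore
  expect_lt(abs(score10 - score5), boundaryFraction(run10$grid) +
    boundaryFraction(g5))
})
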