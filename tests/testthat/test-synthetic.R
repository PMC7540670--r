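# Synthetic scenarios: intensity surfaces, IPP simulation, stylised maps.

test_that("scenarios are deterministic in their seed", {
  s1 <- makeScenario(7); s2 <- makeScenario(7); s3 <- makeScenario(8)
  expect_identical(s1@kernels, s2@kernels)
  expect_false(identical(s1@kernels, s3@kernels))
  g <- makeGrid(s1@region, 15)
  lb <- integrateIntensity(makeIntensity(s1, g), g)
  expect_identical(simulateIPP(lb, g, seed = 4), simulateIPP(lb, g, seed = 4))
  expect_false(identical(simulateIPP(lb, g, seed = 4),
                         simulateIPP(lb, g, seed = 5)))
})

test_that("a single kernel yields a unimodal surface with the analytic mass", {
  sc <- makeScenario(1, baseline = 0,
    kernels = data.frame(lon = -95, lat = 36, amplitude = 0.02, sigmaDeg = 0.4))
  g <- makeGrid(sc@region, 5)
  lam <- makeIntensity(sc, g)
  # peak at the kernel centre cell
  ctr <- cellCenters(g)
  peak <- which.max(lam)
  expect_lt(abs(ctr[peak, 1] - -95), 0.1)
  expect_lt(abs(ctr[peak, 2] - 36), 0.1)
  # analytic Gaussian integral: the kernel is isotropic in local km (lon
  # distances scaled by cos lat), so the lon integral contributes
  # sigma*sqrt(2*pi)/cos(lat) degrees while the area element carries
  # kmPerDeg^2*cos(lat): the cosines cancel and the mass is
  # A * 2*pi*sigma^2 * kmPerDeg^2
  kmPerDeg <- pi * 6371.0072 / 180
  mass <- 0.02 * 2 * pi * 0.4^2 * kmPerDeg^2
  expect_equal(sum(integrateIntensity(lam, g)[gridMask(g)]), mass,
    tolerance = 0.01)
  # zero-amplitude limit: constant baseline
  sc0 <- makeScenario(1, baseline = 1e-4,
    kernels = data.frame(lon = numeric(0), lat = numeric(0),
      amplitude = numeric(0), sigmaDeg = numeric(0)))
  expect_equal(stats::sd(makeIntensity(sc0, g)), 0)
  expect_error(validObject(new("Scenario", seed = 1L, region = sc@region,
    baseline = 0.1, kernels = data.frame(lon = 0, lat = 0, amplitude = -1,
    sigmaDeg = 1), tightStyle = list(), generousStyle = list())), "positive")
})

test_that("simulated counts are Poisson with the surface mass", {
  region <- rectanglePolygon(0, 0, 3, 3)
  g <- makeGrid(region, 30)
  lb <- rep(100 / sum(gridMask(g)), length(gridMask(g)))   # total mass 100
  counts <- vapply(1:200, function(s) nrow(simulateIPP(lb, g, seed = s)),
    numeric(1))
  expect_lt(abs(mean(counts) - 100), 3 * 10 / sqrt(200))
  expect_warning(none <- simulateIPP(rep(0, length(gridMask(g))), g, 1),
    "zero")
  expect_equal(nrow(none), 0L)
  # points land in masked cells, jittered inside
  pts <- simulateIPP(lb, g, seed = 9)
  expect_true(all(!is.na(cellIndex(g, pts))))
})

test_that("thresholding picks exactly the suitable cells", {
  region <- rectanglePolygon(0, 0, 2, 1)
  g <- makeGrid(region, 30)   # 4 x 2
  lb <- ifelse(rep(1:4, 2) <= 2, -log(1 - 0.9), -log(1 - 0.1))  # p = .9 / .1
  s <- occupancyProbability(lb, g)
  map <- makeExpertMap(s, list(threshold = 0.5))
  y <- occupancy(rasterizeMap(map, g))
  expect_equal(y, as.integer(occupancy(s) >= 0.5))
  expect_error(makeExpertMap(s, list(threshold = 0.95)), "no suitable")
})

test_that("convexified maps are convex even for C-shaped suitability", {
  region <- rectanglePolygon(0, 0, 3, 3)
  g <- makeGrid(region, 20)   # 9 x 9
  ci <- rep(1:9, 9); ri <- rep(1:9, each = 9)
  inC <- (ci <= 3) | (ri <= 3) | (ri >= 7)   # C-shape open to the east
  lb <- ifelse(inC, 3, 1e-4)
  s <- occupancyProbability(lb, g)
  mapC <- makeExpertMap(s, list(threshold = 0.5, convexify = FALSE))
  expect_lt(convexHullScore(mapC), 0.9)
  mapConv <- makeExpertMap(s, list(threshold = 0.5, convexify = TRUE))
  expect_equal(convexHullScore(mapConv), 1, tolerance = 1e-9)
})

test_that("generous maps contain tight maps across seeded scenarios", {
  for (seed in 1:20) {
    sc <- makeScenario(seed)
    g <- makeGrid(sc@region, 15)
    s <- occupancyProbability(integrateIntensity(makeIntensity(sc, g), g), g)
    tight <- makeExpertMap(s, sc@tightStyle)
    generous <- makeExpertMap(s, sc@generousStyle)
    verts <- do.call(rbind, polygonRings(tight))
    inside <- rangescore:::.pipRings(verts[, 1], verts[, 2],
      polygonRings(generous))
    expect_true(all(inside))
    expect_gt(unname(geodesicMeasures(generous)["area_km2"]),
      unname(geodesicMeasures(tight)["area_km2"]))
  }
})

test_that("tight maps outscore generous maps on patchy landscapes", {
  wins <- 0L
  for (seed in 1:8) {
    run <- scenarioScores(makeScenario(seed), resolutionArcmin = 15)
    if (run$tight@expertScore > run$generous@expertScore) wins <- wins + 1L
    expect_lt(run$generous@scaledOutside, 0.05)
    expect_gt(run$generous@scaledInside, run$generous@scaledOutside)
  }
  expect_gte(wins, 7L)
})

test_that("synthetic predictor tables honour their coefficients", {
  tab <- syntheticPredictorTable(500, seed = 10, beta = c(x1 = 2, x2 = -1),
    nContinuous = 3, nCategorical = 2, sigma = 0.5)
  expect_equal(nrow(tab), 500L)
  expect_true(all(c("x1", "x2", "x3", "t1", "t2", "y") %in% names(tab)))
  fit <- stats::lm(y ~ x1 + x2 + x3, data = tab)
  expect_equal(unname(stats::coef(fit)["x1"]), 2, tolerance = 0.1)
  expect_equal(unname(stats::coef(fit)["x2"]), -1, tolerance = 0.1)
  expect_error(syntheticPredictorTable(10, 1, beta = c(zz = 1)), "match")
})
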