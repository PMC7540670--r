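# Moran's I, occurrence predictors and AICc multimodel inference.

test_that("a rook checkerboard gives Moran's I of -1", {
  g <- makeGrid(unitSquare(), 15)   # 4 x 4
  chk <- ifelse((rep(1:4, 4) + rep(1:4, each = 4)) %% 2 == 1, 1, -1)
  expect_equal(moransI(chk, g), -1, tolerance = 1e-9)
})

test_that("Moran's I matches a direct-formula oracle on an 8x8 grid", {
  g <- makeGrid(rectanglePolygon(0, 0, 2, 2), 15)   # 8 x 8
  # two solid half-grids of distinct values
  vals <- ifelse(rep(1:8, 8) <= 4, 3, 7)
  W <- rookMatrix(8, 8)
  expect_equal(moransI(vals, g), bruteMoransI(vals, W), tolerance = 1e-12)
  expect_gt(moransI(vals, g), 0.7)
  # a random field agrees with the oracle too, rook and queen
  set.seed(55)
  r <- rnorm(64)
  expect_equal(moransI(r, g), bruteMoransI(r, W), tolerance = 1e-12)
  expect_error(moransI(rep(1, 64), g), "zero variance")
})

test_that("the permutation-null mean of Moran's I is -1/(n-1)", {
  g <- makeGrid(rectanglePolygon(0, 0, 1.5, 1.5), 15)  # 6 x 6, n = 36
  set.seed(66)
  x <- rnorm(36)
  sims <- vapply(1:1000, function(i) moransI(sample(x), g), numeric(1))
  expect_lt(abs(mean(sims) - (-1 / 35)), 3 * stats::sd(sims) / sqrt(1000))
})

test_that("occurrence predictors compute count, density and clustering", {
  sa <- buildStudyArea(mapA = rectanglePolygon(0, 0, 2, 2))
  g <- makeGrid(boundary(sa), 30)   # 4 x 4 cells
  set.seed(77)
  pts <- cbind(runif(50, 0, 2), runif(50, 0, 2))
  pr <- occurrencePredictors(pts, sa, g)
  expect_equal(pr$nPoints, 50L)
  areaKm2 <- unname(geodesicMeasures(boundary(sa))["area_km2"])
  expect_equal(pr$pointDensity, 50 / (areaKm2 / 1e4))
  # all points in one cell: matches the direct-formula oracle
  onecell <- cbind(runif(20, 0.05, 0.45), runif(20, 0.05, 0.45))
  pr2 <- occurrencePredictors(onecell, sa, g)
  counts <- rep(0, 16); counts[1] <- 20
  expect_equal(pr2$moransI, bruteMoransI(counts, rookMatrix(4, 4)),
    tolerance = 1e-12)
  expect_error(occurrencePredictors(cbind(9, 9), sa, g), "no occurrence")
})

test_that("model enumeration is exhaustive over non-empty subsets", {
  expect_length(enumerateModels(paste0("x", 1:3)), 7L)
  expect_length(enumerateModels(paste0("x", 1:11)), 2047L)
  expect_length(enumerateModels("x1"), 1L)
  expect_error(enumerateModels(paste0("x", 1:17)), "guard")
  # brute-force bit enumeration for p = 4
  preds <- paste0("x", 1:4)
  got <- sort(vapply(enumerateModels(preds), function(s)
    paste(sort(s), collapse = "+"), character(1)))
  want <- character(0)
  for (m in 1:15) {
    inc <- as.logical(bitwAnd(m, 2^(0:3)))
    want <- c(want, paste(sort(preds[inc]), collapse = "+"))
  }
  expect_equal(got, sort(want))
})

test_that("AICc, weights and importance match a hand-computed oracle", {
  set.seed(88)
  n <- 24
  tab <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  tab$y <- 1 + 0.8 * tab$x1 - 0.4 * tab$x2 + rnorm(n)
  ens <- fitAndWeigh(tab, "y", c("x1", "x2"))
  # oracle: explicit matrix algebra, no lm()
  oracle <- list()
  for (sub in list("x1", "x2", c("x1", "x2"))) {
    X <- cbind(1, as.matrix(tab[sub]))
    b <- solve(t(X) %*% X, t(X) %*% tab$y)
    rss <- sum((tab$y - X %*% b)^2)
    k <- ncol(X) + 1
    oracle[[paste(sub, collapse = ",")]] <-
      n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
  }
  tbl <- modelTable(ens)
  for (nm in names(oracle))
    expect_equal(tbl$AICc[tbl$terms == nm], oracle[[nm]], tolerance = 1e-9)
  wOracle <- exp(-(unlist(oracle) - min(unlist(oracle))) / 2)
  wOracle <- wOracle / sum(wOracle)
  for (nm in names(oracle))
    expect_equal(tbl$weight[tbl$terms == nm], unname(wOracle[nm]),
      tolerance = 1e-9)
  impOracle <- c(x1 = sum(wOracle[c("x1", "x1,x2")]),
                 x2 = sum(wOracle[c("x2", "x1,x2")]))
  expect_equal(importance(ens), impOracle, tolerance = 1e-9)
  # weights are invariant to a constant shift of AICc
  w2 <- exp(-(tbl$AICc + 42 - min(tbl$AICc + 42)) / 2)
  expect_equal(tbl$weight, w2 / sum(w2), tolerance = 1e-12)
})

test_that("weights are symmetric for equivalent models and sum to one", {
  set.seed(99)
  tab <- data.frame(x1 = rnorm(40))
  tab$x2 <- -tab$x1 + 0   # same information, opposite sign
  tab$y <- tab$x1 + rnorm(40)
  expect_warning(ens <- fitAndWeigh(tab, "y", c("x1", "x2")), "rank-deficient")
  tbl <- modelTable(ens)
  expect_equal(nrow(tbl), 2L)   # the joint model was dropped
  expect_equal(tbl$weight, c(0.5, 0.5), tolerance = 1e-12)
  expect_equal(sum(tbl$weight), 1, tolerance = 1e-12)
  # single-model ensemble has weight 1
  e1 <- fitAndWeigh(tab, "y", "x1")
  expect_equal(modelTable(e1)$weight, 1)
})

test_that("categorical traits enter and leave models as one predictor", {
  tab <- syntheticPredictorTable(120, seed = 5, beta = c(x1 = 1),
    nContinuous = 2, nCategorical = 1, nLevels = 3)
  ens <- fitAndWeigh(tab, "y")
  expect_length(enumerateModels(c("x1", "x2", "t1")), 7L)
  expect_equal(nrow(modelTable(ens)), 7L)
  expect_named(importance(ens), c("x1", "x2", "t1"))
  # dummies consume 2 coefficients: the t1-only model has k = 1+2+1
  expect_equal(modelTable(ens)$k[modelTable(ens)$terms == "t1"], 4L)
  expect_equal(sum(modelTable(ens)$weight), 1, tolerance = 1e-12)
})

test_that("importance separates signal from noise and drives selection", {
  strong <- 0L; weak <- 0L
  for (seed in 1:10) {
    tab <- syntheticPredictorTable(200, seed = seed, beta = c(x1 = 1),
      nContinuous = 2)
    ens <- fitAndWeigh(tab, "y")
    if (importance(ens)["x1"] > 0.99) strong <- strong + 1L
    if (importance(ens)["x2"] < 0.8) weak <- weak + 1L
  }
  expect_equal(strong, 10L)
  expect_gte(weak, 8L)
  # threshold selection and refit
  tab <- syntheticPredictorTable(200, seed = 3, beta = c(x1 = 1),
    nContinuous = 2)
  sel <- selectImportant(fitAndWeigh(tab, "y"), tab)
  expect_equal(sel$predictors, "x1")
  expect_s3_class(sel$model, "lm")
  expect_gte(sel$adjR2Truncated, 0)
  # a pure-noise table usually selects nothing
  null <- syntheticPredictorTable(200, seed = 4, beta = c(x1 = 0),
    nContinuous = 2)
  ensNull <- fitAndWeigh(null, "y")
  if (all(importance(ensNull) < 0.8)) {
    expect_warning(selNull <- selectImportant(ensNull, null), "no predictor")
    expect_length(selNull$predictors, 0L)
  }
})
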