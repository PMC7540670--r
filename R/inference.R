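#' @include grid.R
NULL

#' Moran's I spatial autocorrelation on a grid
#'
#' Moran's I of per-cell values over the masked cells of a grid,
#' I = (n/W) * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i - xbar)^2,
#' with contiguity weights on the study grid, row-standardised by default
#' (then W = n and the leading factor drops out).  Values of +1 indicate
#' perfect clustering of similar values, 0 randomness, -1 perfect clustering
#' of dissimilar values.
#'
#' @param values numeric vector: one value per grid cell, or one value per
#'   masked cell.
#' @param grid a [GridSpec-class].
#' @param style neighbour definition, "rook" (edge-adjacent, default) or
#'   "queen" (edge- or corner-adjacent).
#' @param rowStandardize row-standardise the weights (default TRUE).
#' @return Moran's I (a single number).
#' @examples
#' g <- makeGrid(rectanglePolygon(0, 0, 1, 1), 15)  # 4 x 4 cells
#' chk <- (rep(1:4, 4) + rep(1:4, each = 4)) %% 2
#' moransI(ifelse(chk == 1, 1, -1), g)   # -1: checkerboard
#' @export
moransI <- function(values, grid, style = c("rook", "queen"),
                    rowStandardize = TRUE) {
  style <- match.arg(style)
  m <- grid@mask
  nAll <- grid@nCols * grid@nRows
  if (length(values) == nAll) values <- values[m]
  n <- sum(m)
  if (length(values) != n) stop("values must map onto the grid cells")
  if (n < 2) stop("need at least 2 masked cells")
  x <- as.numeric(values)
  z <- x - mean(x)
  if (sum(z^2) == 0) stop("zero variance: values are constant")
  nb <- .gridNeighbours(grid, style)
  if (nrow(nb) == 0) stop("no neighbour pairs with nonzero weight")
  w <- rep(1, nrow(nb))
  if (rowStandardize) {
    deg <- tabulate(nb[, 1], nbins = n)
    w <- 1 / deg[nb[, 1]]
  }
  W <- sum(w)
  num <- sum(w * z[nb[, 1]] * z[nb[, 2]])
  (n / W) * num / sum(z^2)
}

# directed neighbour pairs (i, j) between masked cells, indexed 1..nMasked
.gridNeighbours <- function(grid, style = "rook") {
  nC <- grid@nCols; nR <- grid@nRows
  m <- grid@mask
  maskedPos <- which(m)
  rank <- integer(nC * nR)
  rank[maskedPos] <- seq_along(maskedPos)
  col <- ((maskedPos - 1) %% nC) + 1
  row <- ((maskedPos - 1) %/% nC) + 1
  offsets <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  if (style == "queen")
    offsets <- c(offsets, list(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1)))
  pairs <- list()
  for (o in offsets) {
    nc2 <- col + o[1]; nr2 <- row + o[2]
    ok <- nc2 >= 1 & nc2 <= nC & nr2 >= 1 & nr2 <= nR
    tgt <- (nr2[ok] - 1) * nC + nc2[ok]
    src <- maskedPos[ok]
    good <- m[tgt]
    pairs[[length(pairs) + 1L]] <- cbind(rank[src[good]], rank[tgt[good]])
  }
  do.call(rbind, pairs)
}

#' Occurrence-geometry predictors
#'
#' The three occurrence-based predictors of expert score: the number of
#' occurrence points in the study area, Moran's I of the per-cell point
#' counts (spatial heterogeneity of the records), and the average point
#' density per 10,000 km2 of study area.
#'
#' @param points 2-column matrix/data.frame of lon/lat records.
#' @param studyArea a [StudyArea-class].
#' @param grid a [GridSpec-class] over the study area.
#' @param style neighbour style for Moran's I.
#' @return a list with \code{nPoints}, \code{moransI} and
#'   \code{pointDensity}.
#' @export
occurrencePredictors <- function(points, studyArea, grid, style = "rook") {
  if (is.data.frame(points)) points <- as.matrix(points[, 1:2])
  idx <- cellIndex(grid, points)
  maskedIdx <- which(grid@mask)
  pos <- match(idx, maskedIdx)
  pos <- pos[!is.na(pos)]
  n <- length(pos)
  if (n == 0) stop("no occurrence points fall inside the study area")
  counts <- tabulate(pos, nbins = length(maskedIdx))
  areaKm2 <- unname(geodesicMeasures(studyArea@boundary)["area_km2"])
  list(nPoints = n,
    moransI = moransI(counts, grid, style = style),
    pointDensity = n / (areaKm2 / 1e4))
}

#' Enumerate all main-effects model subsets
#'
#' All 2^p - 1 non-empty subsets of the predictors, main effects only, no
#' interactions; the intercept is always included when the models are
#' fitted.  With 3 predictors this gives the 7 candidate models (3
#' univariate, 3 bivariate, 1 full); with 11 predictors, 2047 models.
#'
#' @param predictors character vector of predictor names (at most 16).
#' @return list of character vectors, one per candidate model, in bitmask
#'   order.
#' @export
enumerateModels <- function(predictors) {
  p <- length(predictors)
  if (p < 1) stop("need at least one predictor")
  if (p > 16) stop("combinatorial guard: more than 16 predictors")
  lapply(seq_len(2^p - 1), function(massk)
    predictors[bitwAnd(massk, bitwShiftL(1L, seq_len(p) - 1L)) != 0L])
}

# AICc for a least-squares fit: k counts the coefficients plus the residual
# variance (Burnham & Anderson convention).
.aicc <- function(rss, n, nCoef) {
  k <- nCoef + 1
  if (n - k - 1 <= 0) return(NA_real_)
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Exhaustive AICc multimodel inference
#'
#' Fits an ordinary least-squares model for every candidate predictor subset
#' (categoricals dummy-coded; a categorical enters or leaves a model with
#' all its dummies jointly), computes the small-sample-corrected AICc with
#' k equal to the number of coefficients plus one for the residual variance,
#' converts AICc differences into Akaike weights summing to 1, and
#' accumulates per-predictor importance as the summed weight of the models
#' containing each predictor.
#'
#' @param table data.frame holding the response and predictor columns.
#' @param response name of the response column.
#' @param predictors character vector of predictor column names; defaults to
#'   every other column of \code{table}.
#' @return a [ModelEnsemble-class].  Rank-deficient candidate models are
#'   dropped with a warning and the weights renormalised.
#' @examples
#' set.seed(1)
#' d <- data.frame(x1 = rnorm(80), x2 = rnorm(80))
#' d$y <- 2 * d$x1 + rnorm(80)
#' ens <- fitAndWeigh(d, "y")
#' importance(ens)
#' @export
fitAndWeigh <- function(table, response, predictors = NULL) {
  if (!response %in% names(table)) stop("response column not found")
  if (is.null(predictors)) predictors <- setdiff(names(table), response)
  if (anyNA(table[, c(response, predictors)])) stop("missing values in table")
  subsets <- enumerateModels(predictors)
  n <- nrow(table)
  rows <- vector("list", length(subsets))
  dropped <- 0L
  for (i in seq_along(subsets)) {
    fml <- stats::reformulate(subsets[[i]], response = response)
    fit <- stats::lm(fml, data = table)
    cf <- stats::coef(fit)
    if (anyNA(cf)) { dropped <- dropped + 1L; next }
    res <- stats::residuals(fit)
    rss <- sum(res^2)
    aicc <- .aicc(rss, n, length(cf))
    if (!is.finite(aicc))
      stop("AICc undefined: n too small for the model with predictors ",
        paste(subsets[[i]], collapse = ", "))
    rows[[i]] <- data.frame(terms = paste(subsets[[i]], collapse = ","),
      k = length(cf) + 1L, AICc = aicc,
      adjR2 = summary(fit)$adj.r.squared)
  }
  if (dropped > 0)
    warning(dropped, " rank-deficient model(s) dropped; weights renormalised")
  models <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(models) || nrow(models) == 0) stop("no full-rank candidate model")
  delta <- models$AICc - min(models$AICc)
  wRaw <- exp(-delta / 2)
  models$delta <- delta
  models$weight <- wRaw / sum(wRaw)
  models <- models[order(models$AICc), , drop = FALSE]
  rownames(models) <- NULL
  imp <- vapply(predictors, function(pr) {
    inModel <- vapply(strsplit(models$terms, ","), function(tt) pr %in% tt,
      logical(1))
    sum(models$weight[inModel])
  }, numeric(1))
  new("ModelEnsemble", models = models, importance = imp,
    response = response, n = as.integer(n))
}

#' @rdname accessors
#' @export
setMethod("modelTable", "ModelEnsemble", function(x) x@models)

#' @rdname accessors
#' @export
setMethod("importance", "ModelEnsemble", function(x) x@importance)

setMethod("show", "ModelEnsemble", function(object) {
  cat(sprintf("ModelEnsemble: %d models for response '%s' (n = %d)\n",
    nrow(object@models), object@response, object@n))
  cat("importance:\n")
  print(round(sort(object@importance, decreasing = TRUE), 3))
})

#' Select important predictors and refit
#'
#' A predictor is deemed important when the summed Akaike weight of all
#' models containing it reaches the threshold (default 0.8).  The linear
#' model restricted to exactly the important predictors is refitted and
#' returned along with its adjusted R-squared (reported raw and truncated
#' at zero).
#'
#' @param ensemble a [ModelEnsemble-class].
#' @param table the data.frame the ensemble was fitted to.
#' @param threshold importance cutoff (default 0.8).
#' @return list with \code{predictors} (character, possibly empty, with a
#'   warning when empty), \code{model} (an \code{lm} or NULL), \code{adjR2}
#'   and \code{adjR2Truncated}.
#' @export
selectImportant <- function(ensemble, table, threshold = 0.8) {
  sel <- names(ensemble@importance)[ensemble@importance >= threshold]
  if (!length(sel)) {
    warning("no predictor reaches importance >= ", threshold)
    return(list(predictors = character(0), model = NULL,
      adjR2 = NA_real_, adjR2Truncated = NA_real_))
  }
  fit <- stats::lm(stats::reformulate(sel, response = ensemble@response),
    data = table)
  r2 <- summary(fit)$adj.r.squared
  list(predictors = sel, model = fit, adjR2 = r2,
    adjR2Truncated = max(0, r2))
}
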