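#' @include scoring.R
NULL

#' Covariate stack on a grid
#'
#' Packs location-specific covariates (cell-centre values) for the
#' log-linear IPP intensity model, recording the mean and standard deviation
#' of each covariate over the masked cells so that fitting can standardise
#' internally and report coefficients on the original scale.
#'
#' @param grid a [GridSpec-class].
#' @param values matrix or data.frame, one row per grid cell, one column per
#'   covariate (NA allowed outside the mask).
#' @return a [CovariateStack-class].
#' @export
covariateStack <- function(grid, values) {
  if (is.data.frame(values)) values <- as.matrix(values)
  if (is.null(dim(values))) values <- matrix(values, ncol = 1)
  nms <- colnames(values)
  if (is.null(nms)) nms <- paste0("x", seq_len(ncol(values)))
  vm <- values[grid@mask, , drop = FALSE]
  ctr <- colMeans(vm)
  scl <- apply(vm, 2, stats::sd)
  if (any(!is.finite(scl)) || any(scl == 0))
    stop("constant or non-finite covariate inside the mask")
  new("CovariateStack", values = unname(values), names = nms, grid = grid,
    center = unname(ctr), scale = unname(scl))
}

# design matrix over masked cells (original scale), intercept first
.ippDesign <- function(covariates, grid) {
  m <- grid@mask
  if (is.null(covariates)) return(matrix(1, sum(m), 1))
  if (!.sameGrid(covariates@grid, grid)) stop("covariate stack mismatch: different grid")
  cbind(1, covariates@values[m, , drop = FALSE])
}

#' Log-likelihood of a log-linear IPP
#'
#' Berman-Turner quadrature log-likelihood of an inhomogeneous Poisson point
#' process with log-linear intensity:
#' sum_i log lambda(s_i) - sum_j lambda(c_j) a_j, where the first sum runs
#' over the observed points (evaluated at the covariates of the cell holding
#' each point) and the second over the masked quadrature cells with
#' ellipsoidal cell areas a_j.  lambda is in points per km2.
#'
#' @param beta coefficient vector on the original covariate scale, intercept
#'   first.
#' @param points 2-column matrix/data.frame of lon/lat occurrence records.
#' @param covariates a [CovariateStack-class] or NULL for an intercept-only
#'   model.
#' @param grid a [GridSpec-class].
#' @return the log-likelihood in nats.
#' @export
ippLogLik <- function(beta, points, covariates, grid) {
  if (is.data.frame(points)) points <- as.matrix(points[, 1:2])
  X <- .ippDesign(covariates, grid)
  if (length(beta) != ncol(X)) stop("beta length does not match the design")
  idxAll <- cellIndex(grid, points)
  maskedIdx <- which(grid@mask)
  pos <- match(idxAll, maskedIdx)
  if (anyNA(pos)) {
    bad <- which(is.na(pos))
    stop("points outside the study-area mask: rows ",
      paste(utils::head(bad, 10), collapse = ", "),
      if (length(bad) > 10) " ..." else "")
  }
  eta <- drop(X %*% beta)
  a <- grid@cellAreas[maskedIdx]
  sum(eta[pos]) - sum(a * exp(eta))
}

#' Fit a log-linear IPP intensity model
#'
#' Maximises the Berman-Turner quadrature log-likelihood by Newton iteration
#' with analytic gradient and Hessian (the log-likelihood is concave in
#' beta, so the iteration is deterministic and fast).  Covariates are
#' standardised to zero mean / unit variance over the masked cells before
#' fitting; coefficients, their covariance matrix and the log-likelihood are
#' reported on the original scale.
#'
#' For a model with an intercept the score equations enforce
#' sum_j lambda(c_j) a_j = n: the fitted total intensity reproduces the
#' observed point count.
#'
#' @param points 2-column matrix/data.frame of lon/lat occurrence records;
#'   every point must fall in a masked cell.
#' @param covariates a [CovariateStack-class] or NULL (intercept-only).
#' @param grid a [GridSpec-class].
#' @param tol convergence tolerance on the gradient max-norm (default 1e-8,
#'   standardised scale).
#' @param maxIter maximum Newton iterations (default 500).
#' @param minPoints minimum number of points required (default
#'   max(10, 2 * nCovariates)).
#' @return an [IntensityModel-class]; if the iteration fails to converge the
#'   model is returned with \code{converged = FALSE} and a warning.
#' @export
fitIPP <- function(points, covariates = NULL, grid, tol = 1e-8,
                   maxIter = 500, minPoints = NULL) {
  if (is.data.frame(points)) points <- as.matrix(points[, 1:2])
  nCov <- if (is.null(covariates)) 0L else ncol(covariates@values)
  if (is.null(minPoints)) minPoints <- max(10, 2 * nCov)
  n <- nrow(points)
  if (n == 0) stop("no points")
  if (n < minPoints)
    stop("too few points: ", n, " < ", minPoints)
  X <- .ippDesign(covariates, grid)   # original scale
  # standardise covariate columns
  Xs <- X
  if (nCov > 0) {
    Xs[, -1] <- sweep(sweep(X[, -1, drop = FALSE], 2, covariates@center), 2,
      covariates@scale, "/")
  }
  maskedIdx <- which(grid@mask)
  pos <- match(cellIndex(grid, points), maskedIdx)
  if (anyNA(pos)) {
    bad <- which(is.na(pos))
    stop("points outside the study-area mask: rows ",
      paste(utils::head(bad, 10), collapse = ", "),
      if (length(bad) > 10) " ..." else "")
  }
  a <- grid@cellAreas[maskedIdx]
  sumXobs <- colSums(Xs[pos, , drop = FALSE])
  p <- ncol(Xs)
  beta <- c(log(n / sum(a)), rep(0, p - 1))
  loglik <- function(b) {
    eta <- drop(Xs %*% b)
    sum(eta[pos]) - sum(a * exp(eta))
  }
  ll <- loglik(beta)
  grad <- NULL
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    eta <- drop(Xs %*% beta)
    lam <- a * exp(eta)
    grad <- sumXobs - colSums(Xs * lam)
    if (max(abs(grad)) < tol) { converged <- TRUE; break }
    H <- -crossprod(Xs * sqrt(lam))
    step <- tryCatch(solve(H, -grad), error = function(e) grad * 1e-4)
    # step halving to guarantee ascent
    sc <- 1
    repeat {
      cand <- beta + sc * step
      llNew <- loglik(cand)
      if (is.finite(llNew) && llNew >= ll - 1e-12) break
      sc <- sc / 2
      if (sc < 1e-12) { cand <- beta; llNew <- ll; break }
    }
    beta <- cand; ll <- llNew
  }
  if (!converged) {
    eta <- drop(Xs %*% beta)
    grad <- sumXobs - colSums(Xs * (a * exp(eta)))
    converged <- max(abs(grad)) < tol
    if (!converged)
      warning("IPP fit did not converge after ", maxIter,
        " iterations (gradient max-norm ", format(max(abs(grad))), ")")
  }
  eta <- drop(Xs %*% beta)
  lam <- a * exp(eta)
  H <- -crossprod(Xs * sqrt(lam))
  vcovStd <- tryCatch(solve(-H), error = function(e) matrix(NA_real_, p, p))
  # back-transform to the original covariate scale
  nms <- c("(Intercept)", if (nCov > 0) covariates@names)
  if (nCov > 0) {
    Tm <- diag(p)
    Tm[1, -1] <- -covariates@center / covariates@scale
    diag(Tm)[-1] <- 1 / covariates@scale
    betaOrig <- drop(Tm %*% beta)
    vcovOrig <- Tm %*% vcovStd %*% t(Tm)
  } else {
    betaOrig <- beta
    vcovOrig <- vcovStd
  }
  names(betaOrig) <- nms
  dimnames(vcovOrig) <- list(nms, nms)
  new("IntensityModel", beta = betaOrig, betaStd = beta, vcov = vcovOrig,
    covariateNames = if (nCov > 0) covariates@names else character(0),
    logLik = ll, converged = converged, gradNorm = max(abs(grad)),
    nPoints = as.integer(n))
}

setMethod("show", "IntensityModel", function(object) {
  cat(sprintf("IntensityModel (log-linear IPP), n = %d, logLik = %.3f, %s\n",
    object@nPoints, object@logLik,
    if (object@converged) "converged" else "NOT converged"))
  se <- sqrt(diag(object@vcov))
  print(round(cbind(beta = object@beta, se = se), 4))
})

#' Per-cell integrated intensity from a fitted model
#'
#' Predicts lambdaBar_j = lambda(c_j) * a_j for every masked cell: the
#' midpoint-rule integral of the fitted intensity over the cell, which feeds
#' [occupancyProbability()].  For a fitted model with intercept the masked
#' total sum(lambdaBar) equals the observed point count (Poisson MLE score
#' identity).
#'
#' @param model an [IntensityModel-class].
#' @param covariates the [CovariateStack-class] used in fitting (NULL for
#'   intercept-only models).
#' @param grid a [GridSpec-class].
#' @param allowUnconverged set TRUE to predict from a non-converged fit.
#' @return numeric vector with one lambdaBar per grid cell (NA outside the
#'   mask).
#' @export
predictLambdaBar <- function(model, covariates = NULL, grid,
                             allowUnconverged = FALSE) {
  if (!model@converged && !allowUnconverged)
    stop("model did not converge; pass allowUnconverged = TRUE to override")
  nCov <- length(model@covariateNames)
  if (nCov > 0) {
    if (is.null(covariates)) stop("covariate stack mismatch: model has covariates")
    if (!identical(covariates@names, model@covariateNames))
      stop("covariate stack mismatch: names differ")
  } else if (!is.null(covariates)) {
    stop("covariate stack mismatch: model has no covariates")
  }
  X <- .ippDesign(covariates, grid)
  eta <- drop(X %*% model@beta)
  out <- rep(NA_real_, grid@nCols * grid@nRows)
  out[grid@mask] <- exp(eta) * grid@cellAreas[grid@mask]
  out
}
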