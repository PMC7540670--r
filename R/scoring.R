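#' @include grid.R
NULL

#' Occupancy probability from integrated intensity
#'
#' Converts per-cell integrated IPP intensities lambdaBar_j (expected point
#' counts per cell) into occupancy probabilities p_j = 1 - exp(-lambdaBar_j),
#' clamped to [eps, 1 - eps] so the Bernoulli scoring rule stays finite.
#'
#' @param lambdaBar numeric vector of per-cell integrated intensities, one
#'   value per grid cell (NA allowed outside the mask).
#' @param grid a [GridSpec-class].
#' @param clampEps clamping bound (default 1e-10).
#' @return a [ProbabilitySurface-class]; the number of clamped masked cells
#'   is recorded in its \code{nClamped} slot.
#' @examples
#' g <- makeGrid(rectanglePolygon(0, 0, 1, 1), 30)
#' s <- occupancyProbability(rep(log(2), 4), g)
#' occupancy(s)   # all 0.5
#' @export
occupancyProbability <- function(lambdaBar, grid, clampEps = 1e-10) {
  n <- grid@nCols * grid@nRows
  lambdaBar <- rep_len(as.numeric(lambdaBar), n)
  lm <- lambdaBar[grid@mask]
  if (any(!is.finite(lm))) stop("lambdaBar must be finite on all masked cells")
  if (any(lm < 0)) stop("negative lambdaBar")
  p <- -expm1(-lambdaBar)
  clampedLow <- grid@mask & !is.na(p) & p < clampEps
  clampedHigh <- grid@mask & !is.na(p) & p > 1 - clampEps
  p[clampedLow] <- clampEps
  p[clampedHigh] <- 1 - clampEps
  new("ProbabilitySurface", lambdaBar = lambdaBar, p = p, grid = grid,
    clampEps = clampEps, nClamped = sum(clampedLow | clampedHigh))
}

#' @rdname accessors
#' @export
setMethod("occupancy", "ProbabilitySurface", function(x) x@p)

setMethod("show", "ProbabilitySurface", function(object) {
  pm <- object@p[object@grid@mask]
  cat(sprintf("ProbabilitySurface: %d masked cells, p in [%.3g, %.3g], %d clamped (eps = %g)\n",
    length(pm), min(pm), max(pm), object@nClamped, object@clampEps))
})

#' Bernoulli proper scoring rule
#'
#' The per-cell score l(y, p) = -2 [ y log p + (1 - y) log(1 - p) ]: twice
#' the Bernoulli negative log-likelihood of the binary map state y under the
#' occupancy probability p.  It is a proper scoring rule: its expectation is
#' minimised when the stated probability equals the true occupancy
#' probability.  Always non-negative.
#'
#' @param y binary map state(s), 0 or 1 (vectorised).
#' @param p occupancy probability(ies) strictly inside (0, 1); clamping is
#'   the caller's responsibility (see [occupancyProbability()]).
#' @return numeric vector of scores.
#' @examples
#' scoringRule(1, 0.5)    # 2 log 2
#' scoringRule(0, 0.75)   # -2 log 0.25
#' @export
scoringRule <- function(y, p) {
  if (any(!y %in% c(0, 1))) stop("y must be 0 or 1")
  if (any(p <= 0 | p >= 1)) stop("p must lie strictly inside (0, 1); clamp upstream")
  -2 * (y * log(p) + (1 - y) * log1p(-p))
}

#' Quadrature deviance of a binary map against a probability surface
#'
#' Numerical quadrature approximation of the integral of l(y(s), p(s)) over
#' the study area: the per-cell scores are summed over the masked cells with
#' the ellipsoidal cell areas as quadrature weights.  The expert score is
#' invariant to any uniform rescaling of the weights because it is a ratio
#' of two such sums on the same grid.
#'
#' @param y a [BinaryMapGrid-class].
#' @param surface a [ProbabilitySurface-class] on the same grid.
#' @param weights optional per-cell quadrature weights (defaults to the grid
#'   cell areas in km2; pass 1 for unweighted sums).
#' @return the deviance (a single non-negative number).
#' @export
totalDeviance <- function(y, surface, weights = NULL) {
  grid <- y@grid
  if (!.sameGrid(grid, surface@grid)) stop("grid mismatch between map and surface")
  if (is.null(weights)) weights <- grid@cellAreas
  weights <- rep_len(weights, grid@nCols * grid@nRows)
  m <- grid@mask
  sum(scoringRule(y@y[m], surface@p[m]) * weights[m])
}

#' Expert score of a range map against a probability surface
#'
#' The deviance-explained metric at the heart of the package:
#' \deqn{score = 1 - D_{expert} / D_{null}}
#' where both deviances are quadrature sums of the Bernoulli scoring rule
#' over the study area, and the null map covers all of S.  The expert
#' deviance splits exactly into the part inside the map (which, scaled by
#' the null deviance, quantifies commission error) and the part outside
#' (omission error), so that
#' score = 1 - (scaledInside + scaledOutside).
#' A score of 0 means the map is no better than the null map; negative
#' scores are possible when the map predicts worse than the null map.
#'
#' @param map the expert map: a [RangePolygon-class] (rasterized by cell
#'   centre) or an already-rasterized [BinaryMapGrid-class].
#' @param surface a [ProbabilitySurface-class].
#' @param weights optional quadrature weights, as in [totalDeviance()].
#' @return a [DevianceResult-class].
#' @examples
#' g <- makeGrid(rectanglePolygon(0, 0, 1, 1), 10)
#' s <- occupancyProbability(runif(36, 0.1, 2), g)
#' expertScore(rectanglePolygon(0, 0, 1, 1), s)@expertScore   # exactly 0
#' @export
expertScore <- function(map, surface, weights = NULL) {
  grid <- surface@grid
  yGrid <- if (is(map, "BinaryMapGrid")) map else rasterizeMap(map, grid)
  if (!.sameGrid(yGrid@grid, grid)) stop("grid mismatch between map and surface")
  if (is.null(weights)) weights <- grid@cellAreas
  weights <- rep_len(weights, grid@nCols * grid@nRows)
  m <- grid@mask
  y <- yGrid@y[m]; p <- surface@p[m]; w <- weights[m]
  lExpert <- scoringRule(y, p) * w
  lNull <- scoringRule(rep(1L, length(p)), p) * w
  devNull <- sum(lNull)
  if (devNull <= length(p) * 4 * surface@clampEps * max(w))
    stop("degenerate surface: null deviance is numerically zero (all p at the upper clamp)")
  inside <- y == 1L
  devInside <- sum(lExpert[inside])
  devOutside <- sum(lExpert[!inside])
  devExpert <- sum(lExpert)
  new("DevianceResult",
    devianceExpert = devExpert, devianceNull = devNull,
    devianceInside = devInside, devianceOutside = devOutside,
    scaledInside = devInside / devNull, scaledOutside = devOutside / devNull,
    expertScore = 1 - devExpert / devNull)
}

setMethod("show", "DevianceResult", function(object) {
  cat("DevianceResult\n")
  cat(sprintf("  expert score     : %.4f\n", object@expertScore))
  cat(sprintf("  scaled inside    : %.4f (commission)\n", object@scaledInside))
  cat(sprintf("  scaled outside   : %.4f (omission)\n", object@scaledOutside))
  cat(sprintf("  deviance expert  : %.6g\n", object@devianceExpert))
  cat(sprintf("  deviance null    : %.6g\n", object@devianceNull))
})

#' @describeIn DevianceResult-class flatten to a one-row data.frame with the
#'   seven deviance/score fields.
#' @param x a DevianceResult.
#' @param row.names,optional,... ignored (S3 compatibility).
#' @export
as.data.frame.DevianceResult <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(deviance_expert = x@devianceExpert, deviance_null = x@devianceNull,
    deviance_inside = x@devianceInside, deviance_outside = x@devianceOutside,
    scaled_inside = x@scaledInside, scaled_outside = x@scaledOutside,
    expert_score = x@expertScore)
}
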