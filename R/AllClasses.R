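#' @import methods
NULL

#' RangePolygon: a multipolygon range map in lon/lat
#'
#' Container for an expert range map (or any study-region boundary) as a set
#' of polygon rings in geographic coordinates (decimal degrees, WGS84,
#' lon/lat order).  Rings are stored open (last vertex is not a repeat of the
#' first) and are classified as shells or holes; holes subtract from the
#' geodesic area and add to the perimeter.
#'
#' @slot rings list of numeric matrices, one per ring, two columns (lon, lat).
#' @slot hole logical vector, one flag per ring; \code{TRUE} marks a hole.
#' @slot label free-text source tag (e.g. the map provider).
#'
#' @seealso [RangePolygon()] for the user constructor,
#'   [geodesicMeasures()], [expertAgreement()].
#' @export
setClass("RangePolygon",
  representation(rings = "list", hole = "logical", label = "character"),
  prototype(rings = list(), hole = logical(0), label = ""))

setValidity("RangePolygon", function(object) {
  msgs <- character(0)
  if (length(object@rings) != length(object@hole))
    msgs <- c(msgs, "one hole flag is required per ring")
  for (r in object@rings) {
    if (!is.matrix(r) || ncol(r) != 2 || !is.numeric(r))
      return("each ring must be a numeric matrix with columns lon, lat")
    if (nrow(r) < 3) msgs <- c(msgs, "rings need at least 3 vertices")
    if (any(!is.finite(r))) msgs <- c(msgs, "non-finite coordinates")
    else {
      if (any(r[, 2] < -90 | r[, 2] > 90)) msgs <- c(msgs, "latitude outside [-90, 90]")
      if (any(r[, 1] < -360 | r[, 1] > 360)) msgs <- c(msgs, "longitude outside [-360, 360]")
      if (diff(range(r[, 1])) > 180)
        msgs <- c(msgs, "ring spans more than 180 degrees of longitude (antimeridian-crossing ranges are not supported)")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' StudyArea: the region S over which maps are scored
#'
#' The study area is the convex hull of the union of an alpha hull around the
#' occurrence records and the expert maps, clipped to land.  It carries a
#' provenance record of how it was built.
#'
#' @slot boundary a [RangePolygon-class] delimiting S.
#' @slot provenance named list recording the construction inputs (alpha
#'   parameter in degrees, number of occurrence points, clip-boundary label).
#' @export
setClass("StudyArea",
  representation(boundary = "RangePolygon", provenance = "list"),
  prototype(provenance = list()))

#' GridSpec: an axis-aligned lon/lat quadrature grid
#'
#' Regular graticule-aligned grid used as the quadrature partition of the
#' study area.  Cells are indexed row-major from the south-west corner
#' (index = (row - 1) * nCols + col).  Cell membership in the study area is
#' decided by cell-centre containment; cell intervals are half-open,
#' [west, east) x [south, north).
#'
#' @slot resolutionArcmin cell size in arc minutes.
#' @slot west,south western and southern edge of the grid (degrees), snapped
#'   to multiples of the resolution.
#' @slot nCols,nRows grid dimensions.
#' @slot mask logical, length nCols * nRows; TRUE for cells inside the study
#'   area.
#' @slot cellAreas numeric, ellipsoidal cell areas in km2 (latitude band
#'   formula; constant within a row).
#' @export
setClass("GridSpec",
  representation(resolutionArcmin = "numeric", west = "numeric",
    south = "numeric", nCols = "integer", nRows = "integer",
    mask = "logical", cellAreas = "numeric"))

setValidity("GridSpec", function(object) {
  n <- object@nCols * object@nRows
  if (length(object@mask) != n) return("mask length must equal nCols * nRows")
  if (length(object@cellAreas) != n) return("cellAreas length must equal nCols * nRows")
  if (object@resolutionArcmin <= 0) return("resolution must be positive")
  if (any(object@cellAreas <= 0)) return("cell areas must be positive")
  TRUE
})

#' BinaryMapGrid: a rasterized binary map y_j on a grid
#'
#' Per-cell indicator of the binary map process y(s): 1 where the map declares
#' the species present, 0 elsewhere.  Values are defined for every cell;
#' cells outside the study-area mask are ignored by all scoring sums.
#'
#' @slot y integer vector of 0/1, length nCols * nRows of the grid.
#' @slot grid the [GridSpec-class] the values live on.
#' @export
setClass("BinaryMapGrid",
  representation(y = "integer", grid = "GridSpec"))

setValidity("BinaryMapGrid", function(object) {
  if (length(object@y) != object@grid@nCols * object@grid@nRows)
    return("y length must match the grid")
  if (any(!object@y[object@grid@mask] %in% c(0L, 1L)))
    return("y must be 0/1 on all masked cells")
  TRUE
})

#' ProbabilitySurface: per-cell occupancy probabilities
#'
#' Occupancy probability p_j = 1 - exp(-lambdaBar_j) derived from the per-cell
#' integrated intensity of an inhomogeneous Poisson process, clamped to
#' [eps, 1 - eps] so the scoring rule stays finite.
#'
#' @slot lambdaBar numeric, integrated intensity per cell (expected point
#'   count in the cell); NA allowed outside the mask.
#' @slot p numeric, clamped occupancy probability per cell.
#' @slot grid the [GridSpec-class].
#' @slot clampEps clamping bound used.
#' @slot nClamped number of masked cells whose probability hit a clamp bound.
#' @export
setClass("ProbabilitySurface",
  representation(lambdaBar = "numeric", p = "numeric", grid = "GridSpec",
    clampEps = "numeric", nClamped = "integer"))

setValidity("ProbabilitySurface", function(object) {
  n <- object@grid@nCols * object@grid@nRows
  if (length(object@p) != n || length(object@lambdaBar) != n)
    return("lambdaBar and p must have one value per grid cell")
  pm <- object@p[object@grid@mask]
  if (any(!is.finite(pm))) return("p must be finite on all masked cells")
  if (any(pm <= 0 | pm >= 1)) return("p must lie strictly inside (0, 1) after clamping")
  TRUE
})

#' DevianceResult: deviances, decomposition and expert score
#'
#' Output of [expertScore()]: the quadrature deviance of the expert map and of
#' the null map (the map covering all of S), the inside/outside split of the
#' expert deviance, the null-scaled commission and omission components, and
#' the deviance-explained expert score.
#'
#' @slot devianceExpert,devianceNull,devianceInside,devianceOutside raw
#'   quadrature deviances (score units times km2).
#' @slot scaledInside scaled deviance inside the map (commission component).
#' @slot scaledOutside scaled deviance outside the map (omission component).
#' @slot expertScore 1 - devianceExpert / devianceNull; at most 1, negative
#'   when the map predicts worse than the null map.
#' @export
setClass("DevianceResult",
  representation(devianceExpert = "numeric", devianceNull = "numeric",
    devianceInside = "numeric", devianceOutside = "numeric",
    scaledInside = "numeric", scaledOutside = "numeric",
    expertScore = "numeric"))

#' CovariateStack: location-specific covariates on a grid
#'
#' Cell-centre covariate values used by the log-linear IPP intensity model,
#' with the standardisation (mean/sd inside the mask) recorded so
#' coefficients can be reported on the original scale.
#'
#' @slot values numeric matrix, nCells x nCovariates; NA allowed outside the
#'   mask.
#' @slot names covariate names.
#' @slot grid the [GridSpec-class].
#' @slot center,scale per-covariate standardisation parameters (computed over
#'   masked cells).
#' @export
setClass("CovariateStack",
  representation(values = "matrix", names = "character", grid = "GridSpec",
    center = "numeric", scale = "numeric"))

setValidity("CovariateStack", function(object) {
  if (nrow(object@values) != object@grid@nCols * object@grid@nRows)
    return("covariate values must have one row per grid cell")
  if (ncol(object@values) != length(object@names))
    return("one name per covariate column is required")
  if (any(!is.finite(object@values[object@grid@mask, , drop = FALSE])))
    return("covariates must be finite on all masked cells")
  TRUE
})

#' IntensityModel: a fitted log-linear IPP intensity
#'
#' Maximum-likelihood fit of log lambda(s) = beta0 + sum_k beta_k x_k(s) to a
#' point pattern, via Newton iteration on the Berman-Turner quadrature
#' log-likelihood.  Coefficients are stored on the original covariate scale;
#' the standardised-scale coefficients used internally are kept alongside.
#'
#' @slot beta named coefficients on the original covariate scale (first is
#'   the intercept).
#' @slot betaStd coefficients on the standardised scale.
#' @slot vcov variance-covariance matrix of beta (original scale, from the
#'   observed information).
#' @slot covariateNames names of the covariates (without intercept).
#' @slot logLik maximised log-likelihood (nats).
#' @slot converged logical convergence flag.
#' @slot gradNorm gradient max-norm at the returned estimate.
#' @slot nPoints number of points used.
#' @export
setClass("IntensityModel",
  representation(beta = "numeric", betaStd = "numeric", vcov = "matrix",
    covariateNames = "character", logLik = "numeric", converged = "logical",
    gradNorm = "numeric", nPoints = "integer"))

#' ModelEnsemble: exhaustively enumerated OLS models with AICc weights
#'
#' All-subsets main-effects linear models for one response, with AICc, Akaike
#' weights and per-predictor importance (the summed weight of the models that
#' contain the predictor).
#'
#' @slot models data.frame with one row per fitted model: terms (comma
#'   separated), k (number of estimated parameters including the residual
#'   variance), AICc, delta, weight, adjR2.
#' @slot importance named numeric vector of per-predictor summed weights.
#' @slot response name of the response column.
#' @slot n number of rows the models were fitted to.
#' @export
setClass("ModelEnsemble",
  representation(models = "data.frame", importance = "numeric",
    response = "character", n = "integer"))

setValidity("ModelEnsemble", function(object) {
  if (nrow(object@models) > 0 && abs(sum(object@models$weight) - 1) > 1e-8)
    return("Akaike weights must sum to 1")
  if (length(object@importance) &&
      any(object@importance < -1e-12 | object@importance > 1 + 1e-12))
    return("importances must lie in [0, 1]")
  TRUE
})

#' Scenario: a seeded synthetic study condition
#'
#' Fully deterministic description of a synthetic scenario: a rectangular
#' region, a Gaussian-kernel intensity surface (points per km2), and the two
#' stylised expert-map drawing styles ("tight" maps keep the thresholded
#' suitable cells with their detail; "generous" maps convexify and dilate,
#' emulating range maps that sweep in every area the species reaches).
#'
#' @slot seed integer seed driving all randomness derived from the scenario.
#' @slot region rectangular [RangePolygon-class] the scenario lives in.
#' @slot baseline background intensity, points per km2.
#' @slot kernels data.frame with columns lon, lat, amplitude (points per km2
#'   at the peak), sigmaDeg (kernel length scale, degrees).
#' @slot tightStyle,generousStyle named lists with elements threshold,
#'   dilationDeg, simplifyDeg, convexify.
#' @export
setClass("Scenario",
  representation(seed = "integer", region = "RangePolygon",
    baseline = "numeric", kernels = "data.frame",
    tightStyle = "list", generousStyle = "list"))

setValidity("Scenario", function(object) {
  need <- c("lon", "lat", "amplitude", "sigmaDeg")
  if (!all(need %in% names(object@kernels)))
    return("kernels need columns lon, lat, amplitude, sigmaDeg")
  if (nrow(object@kernels) && any(object@kernels$amplitude <= 0))
    return("kernel amplitudes must be positive")
  if (object@baseline < 0) return("baseline intensity must be non-negative")
  TRUE
})
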