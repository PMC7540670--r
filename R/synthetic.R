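#' @include scoring.R agreement.R
NULL

# run an expression with a locally seeded RNG, restoring global state after
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Construct a synthetic scenario
#'
#' Creates a [Scenario-class]: a rectangular region holding a patchy
#' Gaussian-kernel intensity surface plus the parameters of the two expert
#' map styles.  With \code{kernels = NULL} the kernel centres, amplitudes
#' and length scales are drawn from the seeded RNG, producing a patchy
#' suitability landscape (several distinct high-intensity patches over a
#' near-zero background) of the kind that separates tight from generous
#' map-drawing styles.
#'
#' Defaults describe a mid-latitude region of about 10 x 8 degrees with
#' kernel intensities high enough that occupancy probability approaches 1
#' in patch cores at a 10-arcmin grid while the background stays near 0.
#'
#' @param seed integer seed; all randomness derived from the scenario is a
#'   deterministic function of it.
#' @param region rectangular [RangePolygon-class] (default lon -100..-90,
#'   lat 32..40).
#' @param nKernels number of suitability patches drawn when
#'   \code{kernels = NULL} (default 6).
#' @param baseline background intensity in points per km2 (default 2e-5).
#' @param kernels optional data.frame(lon, lat, amplitude, sigmaDeg)
#'   overriding the random draw.
#' @param tightStyle,generousStyle style parameter lists; see
#'   [makeExpertMap()].
#' @return a [Scenario-class].
#' @examples
#' sc <- makeScenario(7)
#' sc
#' @export
makeScenario <- function(seed, region = rectanglePolygon(-100, 32, -90, 40,
    label = "synthetic region"), nKernels = 6, baseline = 2e-5,
    kernels = NULL,
    tightStyle = list(threshold = 0.5, dilationDeg = 0, simplifyDeg = 0,
      convexify = FALSE),
    generousStyle = list(threshold = 0.05, dilationDeg = 1, simplifyDeg = 0,
      convexify = TRUE)) {
  seed <- as.integer(seed)
  if (is.null(kernels)) {
    bb <- .bboxRing(region@rings[[1]])
    kernels <- .withSeed(seed, {
      # keep patch centres away from the region edge by half a degree
      data.frame(
        lon = stats::runif(nKernels, bb[1] + 0.5, bb[3] - 0.5),
        lat = stats::runif(nKernels, bb[2] + 0.5, bb[4] - 0.5),
        amplitude = stats::runif(nKernels, 0.01, 0.03),
        sigmaDeg = stats::runif(nKernels, 0.3, 0.8))
    })
  }
  new("Scenario", seed = seed, region = region, baseline = baseline,
    kernels = kernels, tightStyle = tightStyle, generousStyle = generousStyle)
}

setMethod("show", "Scenario", function(object) {
  cat(sprintf("Scenario (seed %d): %d kernel(s), baseline %.2g pts/km2\n",
    object@seed, nrow(object@kernels), object@baseline))
})

#' Intensity surface of a scenario
#'
#' Evaluates the scenario intensity lambda(s), in points per km2, at the
#' cell centres of a grid: a constant baseline plus a sum of isotropic
#' Gaussian kernels in degree space (longitude distances scaled by the
#' cosine of the kernel latitude).  Strictly positive whenever baseline > 0.
#'
#' @param scenario a [Scenario-class].
#' @param grid a [GridSpec-class] over the scenario region.
#' @return numeric vector of intensities, one per grid cell.
#' @export
makeIntensity <- function(scenario, grid) {
  if (nrow(scenario@kernels) && any(scenario@kernels$amplitude <= 0))
    stop("non-positive kernel amplitude")
  ctr <- cellCenters(grid)
  lam <- rep(scenario@baseline, nrow(ctr))
  for (k in seq_len(nrow(scenario@kernels))) {
    kk <- scenario@kernels[k, ]
    dx <- (ctr[, 1] - kk$lon) * cos(kk$lat * pi / 180)
    dy <- ctr[, 2] - kk$lat
    lam <- lam + kk$amplitude * exp(-(dx^2 + dy^2) / (2 * kk$sigmaDeg^2))
  }
  lam
}

#' Integrate an intensity over the grid cells
#'
#' Midpoint-rule integration: lambdaBar_j = lambda(c_j) * a_j with a_j the
#' ellipsoidal cell area in km2.  Cells outside the mask get NA.
#'
#' @param lambda per-cell intensity in points per km2.
#' @param grid a [GridSpec-class].
#' @return per-cell integrated intensity (expected count per cell).
#' @export
integrateIntensity <- function(lambda, grid) {
  out <- rep(NA_real_, grid@nCols * grid@nRows)
  out[grid@mask] <- lambda[grid@mask] * grid@cellAreas[grid@mask]
  out
}

#' Simulate an inhomogeneous Poisson point pattern
#'
#' Draws a point pattern from the IPP with the given per-cell integrated
#' intensity: the total count is Poisson with mean sum(lambdaBar), cells are
#' chosen multinomially proportional to lambdaBar, and points are jittered
#' uniformly within their cell.  Fully reproducible for a given seed.
#'
#' @param lambdaBar per-cell integrated intensity (NA outside the mask).
#' @param grid a [GridSpec-class].
#' @param seed integer seed.
#' @return data.frame with columns lon, lat (possibly 0 rows; total mass 0
#'   gives an empty pattern with a warning).
#' @export
simulateIPP <- function(lambdaBar, grid, seed) {
  m <- grid@mask
  lb <- lambdaBar[m]
  if (any(!is.finite(lb))) stop("lambdaBar must be finite on masked cells")
  total <- sum(lb)
  if (total <= 0) {
    warning("total intensity mass is zero; returning an empty pattern")
    return(data.frame(lon = numeric(0), lat = numeric(0)))
  }
  res <- grid@resolutionArcmin / 60
  maskedIdx <- which(m)
  .withSeed(seed, {
    n <- stats::rpois(1, total)
    if (n == 0) {
      data.frame(lon = numeric(0), lat = numeric(0))
    } else {
      cells <- sample(maskedIdx, n, replace = TRUE, prob = lb)
      ci <- ((cells - 1) %% grid@nCols)
      ri <- ((cells - 1) %/% grid@nCols)
      data.frame(
        lon = grid@west + (ci + stats::runif(n)) * res,
        lat = grid@south + (ri + stats::runif(n)) * res)
    }
  })
}

#' Draw a stylised expert map from a probability surface
#'
#' Emulates the two map-drawing philosophies found in published expert
#' maps.  Cells with occupancy probability at or above the threshold are
#' selected and polygonised; a "tight" style keeps the resulting detailed
#' boundary (maps restricted to where the species reliably occurs), while a
#' "generous" style replaces it by its convex hull and dilates it (maps
#' sweeping in every area the species reaches).
#'
#' @param surface a [ProbabilitySurface-class].
#' @param style named list with \code{threshold} in (0,1),
#'   \code{dilationDeg} (convex dilation radius, degrees; applied after
#'   convexification), \code{simplifyDeg} (Douglas-Peucker tolerance,
#'   degrees) and \code{convexify} (logical).
#' @param label label of the returned map.
#' @return a [RangePolygon-class].
#' @export
makeExpertMap <- function(surface, style, label = "expert map") {
  thr <- style$threshold
  if (is.null(thr) || thr <= 0 || thr >= 1) stop("threshold must be in (0, 1)")
  dil <- if (is.null(style$dilationDeg)) 0 else style$dilationDeg
  simp <- if (is.null(style$simplifyDeg)) 0 else style$simplifyDeg
  convexify <- isTRUE(style$convexify)
  grid <- surface@grid
  sel <- grid@mask & !is.na(surface@p) & surface@p >= thr
  if (!any(sel)) stop("no suitable cells: no masked cell reaches the threshold")
  if (convexify) {
    idx <- which(sel)
    ci <- (idx - 1) %% grid@nCols
    ri <- (idx - 1) %/% grid@nCols
    res <- grid@resolutionArcmin / 60
    # corners of all selected cells
    corners <- rbind(
      cbind(grid@west + ci * res, grid@south + ri * res),
      cbind(grid@west + (ci + 1) * res, grid@south + ri * res),
      cbind(grid@west + (ci + 1) * res, grid@south + (ri + 1) * res),
      cbind(grid@west + ci * res, grid@south + (ri + 1) * res))
    ring <- .convexHullXY(corners)
    if (dil > 0) ring <- .bufferConvexRing(ring, dil)
    if (simp > 0) ring <- .rdpSimplify(ring, simp)
    return(RangePolygon(ring, label = label))
  }
  occ <- matrix(sel, nrow = grid@nCols)
  rings <- .traceCellRings(occ, grid@west, grid@south, grid@resolutionArcmin / 60)
  if (!length(rings)) stop("polygonisation failed")
  if (simp > 0) rings <- lapply(rings, .rdpSimplify, tol = simp)
  if (dil > 0)
    warning("dilation of non-convex maps is not supported; dilationDeg ignored")
  RangePolygon(rings, label = label)
}

#' Run a full synthetic scenario end to end
#'
#' Builds the grid over the scenario region, evaluates the intensity and
#' occupancy-probability surface, draws the tight-style and generous-style
#' expert maps, and scores both against the surface.  This is the synthetic
#' analogue of the two-expert comparison: across patchy scenarios the tight
#' map avoids unsuitable cells (low commission) while the generous map
#' includes them, so the tight map is expected to attain the higher expert
#' score with the generous deficit loading on the scaled-inside component.
#'
#' @param scenario a [Scenario-class].
#' @param resolutionArcmin grid resolution (default 10).
#' @param clampEps probability clamp (default 1e-10).
#' @return list with elements \code{grid}, \code{surface}, \code{tightMap},
#'   \code{generousMap}, \code{tight} and \code{generous} (both
#'   [DevianceResult-class]), and \code{agreement} (between the two maps).
#' @export
scenarioScores <- function(scenario, resolutionArcmin = 10, clampEps = 1e-10) {
  grid <- makeGrid(scenario@region, resolutionArcmin)
  lam <- makeIntensity(scenario, grid)
  surface <- occupancyProbability(integrateIntensity(lam, grid), grid, clampEps)
  tightMap <- makeExpertMap(surface, scenario@tightStyle, label = "tight")
  generousMap <- makeExpertMap(surface, scenario@generousStyle, label = "generous")
  list(grid = grid, surface = surface,
    tightMap = tightMap, generousMap = generousMap,
    tight = expertScore(tightMap, surface),
    generous = expertScore(generousMap, surface),
    agreement = expertAgreement(tightMap, generousMap))
}

#' Synthetic predictor table for multimodel inference
#'
#' Simulates a species-by-predictor table of the shape consumed by
#' [fitAndWeigh()]: continuous predictors (standard normal), optional
#' categorical traits with random levels, and a linear response with
#' Gaussian noise.
#'
#' @param n number of rows (species).
#' @param seed integer seed.
#' @param beta named numeric vector of true coefficients for (a subset of)
#'   the continuous predictors.
#' @param nContinuous number of continuous predictors (named x1, x2, ...).
#' @param nCategorical number of categorical trait columns (named t1, ...),
#'   each with \code{nLevels} random levels and no effect on the response.
#' @param nLevels levels per categorical trait.
#' @param sigma residual standard deviation of the response.
#' @param response name of the response column.
#' @return a data.frame.
#' @export
syntheticPredictorTable <- function(n, seed, beta = c(x1 = 1),
    nContinuous = max(3, length(beta)), nCategorical = 0, nLevels = 3,
    sigma = 1, response = "y") {
  .withSeed(seed, {
    tab <- as.data.frame(matrix(stats::rnorm(n * nContinuous), n, nContinuous))
    names(tab) <- paste0("x", seq_len(nContinuous))
    if (nCategorical > 0) {
      for (k in seq_len(nCategorical))
        tab[[paste0("t", k)]] <- factor(sample(LETTERS[seq_len(nLevels)], n,
          replace = TRUE))
    }
    mu <- rep(0, n)
    for (nm in names(beta)) {
      if (!nm %in% names(tab)) stop("beta names must match predictor columns")
      mu <- mu + beta[[nm]] * tab[[nm]]
    }
    tab[[response]] <- mu + stats::rnorm(n, sd = sigma)
    tab
  })
}
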