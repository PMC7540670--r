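#' @include hulls.R
NULL

.makeGridFromBoundary <- function(bnd, resolutionArcmin) {
  if (resolutionArcmin <= 0) stop("resolution must be positive")
  if (.isEmptyPolygon(bnd)) stop("study area is empty")
  res <- resolutionArcmin / 60
  allPts <- do.call(rbind, bnd@rings)
  west <- floor(min(allPts[, 1]) / res) * res
  south <- floor(min(allPts[, 2]) / res) * res
  east <- ceiling(max(allPts[, 1]) / res) * res
  north <- ceiling(max(allPts[, 2]) / res) * res
  nCols <- max(1L, as.integer(round((east - west) / res)))
  nRows <- max(1L, as.integer(round((north - south) / res)))
  cx <- west + (seq_len(nCols) - 0.5) * res
  cy <- south + (seq_len(nRows) - 0.5) * res
  px <- rep(cx, times = nRows)
  py <- rep(cy, each = nCols)
  mask <- .pipRings(px, py, bnd@rings)
  if (!any(mask)) stop("grid too coarse: no cell centre falls inside the study area")
  rowAreas <- .cellAreaKm2(cy - res / 2, cy + res / 2, res)
  areas <- rep(rowAreas, each = nCols)
  new("GridSpec", resolutionArcmin = resolutionArcmin, west = west,
    south = south, nCols = nCols, nRows = nRows, mask = mask,
    cellAreas = areas)
}

#' @rdname makeGrid
setMethod("makeGrid", "StudyArea", function(x, resolutionArcmin = 10)
  .makeGridFromBoundary(x@boundary, resolutionArcmin))

#' @rdname makeGrid
setMethod("makeGrid", "RangePolygon", function(x, resolutionArcmin = 10)
  .makeGridFromBoundary(x, resolutionArcmin))

#' @rdname accessors
#' @export
setMethod("gridMask", "GridSpec", function(x) x@mask)

#' @rdname accessors
#' @export
setMethod("cellAreas", "GridSpec", function(x) x@cellAreas)

#' @rdname accessors
#' @export
setMethod("cellCenters", "GridSpec", function(x) {
  res <- x@resolutionArcmin / 60
  cx <- x@west + (seq_len(x@nCols) - 0.5) * res
  cy <- x@south + (seq_len(x@nRows) - 0.5) * res
  cbind(lon = rep(cx, times = x@nRows), lat = rep(cy, each = x@nCols))
})

setMethod("show", "GridSpec", function(object) {
  cat(sprintf("GridSpec: %d x %d cells at %.3g arcmin, %d masked (%.1f km2)\n",
    object@nCols, object@nRows, object@resolutionArcmin, sum(object@mask),
    sum(object@cellAreas[object@mask])))
})

#' Cell index of lon/lat points on a grid
#'
#' Maps points to row-major cell indices using the half-open cell convention
#' [west, east) x [south, north).  Points outside the grid extent get NA.
#'
#' @param grid a [GridSpec-class].
#' @param points 2-column matrix or data.frame of lon/lat.
#' @return integer vector of cell indices (NA outside the grid).
#' @export
cellIndex <- function(grid, points) {
  if (is.data.frame(points)) points <- as.matrix(points[, 1:2])
  res <- grid@resolutionArcmin / 60
  ci <- floor((points[, 1] - grid@west) / res) + 1
  ri <- floor((points[, 2] - grid@south) / res) + 1
  ok <- ci >= 1 & ci <= grid@nCols & ri >= 1 & ri <= grid@nRows
  idx <- ifelse(ok, (ri - 1) * grid@nCols + ci, NA_integer_)
  as.integer(idx)
}

#' Rasterize a range map onto a grid
#'
#' Discretizes the binary map process y(s) onto the quadrature cells:
#' y_j = 1 iff the cell centre lies inside the map (even-odd rule across
#' rings, so holes rasterize as absence).  An empty map gives all zeros.
#'
#' @param map a [RangePolygon-class] (may be empty).
#' @param grid a [GridSpec-class].
#' @return a [BinaryMapGrid-class].
#' @export
rasterizeMap <- function(map, grid) {
  centers <- cellCenters(grid)
  y <- if (is.null(map) || .isEmptyPolygon(map)) {
    rep(0L, nrow(centers))
  } else {
    as.integer(.pipRings(centers[, 1], centers[, 2], map@rings))
  }
  new("BinaryMapGrid", y = y, grid = grid)
}

#' @rdname accessors
#' @export
setMethod("occupancy", "BinaryMapGrid", function(x) x@y)

setMethod("show", "BinaryMapGrid", function(object) {
  cat(sprintf("BinaryMapGrid: %d of %d masked cells occupied\n",
    sum(object@y[object@grid@mask]), sum(object@grid@mask)))
})

#' Boundary fraction of a grid mask
#'
#' Fraction of the masked area lying in cells adjacent (queen neighbourhood)
#' to unmasked or off-grid cells.  This is the reported discretization bound:
#' refining the grid can only reassign boundary cells, so score differences
#' between resolutions are expected to stay below this fraction for smooth
#' surfaces.
#'
#' @param grid a [GridSpec-class].
#' @return a single number in [0, 1].
#' @export
boundaryFraction <- function(grid) {
  m <- matrix(grid@mask, nrow = grid@nCols)
  nC <- grid@nCols; nR <- grid@nRows
  pad <- matrix(FALSE, nC + 2, nR + 2)
  pad[2:(nC + 1), 2:(nR + 1)] <- m
  isBoundary <- matrix(FALSE, nC, nR)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    nb <- pad[(2:(nC + 1)) + di, (2:(nR + 1)) + dj, drop = FALSE]
    isBoundary <- isBoundary | (m & !nb)
  }
  a <- grid@cellAreas
  sum(a[as.vector(isBoundary)]) / sum(a[grid@mask])
}

.sameGrid <- function(g1, g2) {
  isTRUE(all.equal(g1@resolutionArcmin, g2@resolutionArcmin)) &&
    isTRUE(all.equal(g1@west, g2@west)) &&
    isTRUE(all.equal(g1@south, g2@south)) &&
    g1@nCols == g2@nCols && g1@nRows == g2@nRows
}
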