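#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a RangePolygon
#'
#' Builds a [RangePolygon-class] from one ring matrix or a list of ring
#' matrices (two columns, lon/lat decimal degrees, WGS84).  Rings may be open
#' or closed on input; consecutive duplicate vertices and zero-area rings are
#' dropped.  Unless \code{hole} is supplied, rings are classified as shells
#' or holes by even-odd containment parity (a ring contained in an odd number
#' of other rings is a hole).
#'
#' @param coords a 2-column numeric matrix, a data.frame with lon/lat in the
#'   first two columns, or a list of such matrices (one per ring).
#' @param label free-text source tag.
#' @param hole optional logical vector, one flag per ring, overriding the
#'   parity classification.
#' @return a [RangePolygon-class].
#' @examples
#' sq <- RangePolygon(cbind(c(0, 2, 2, 0), c(0, 0, 2, 2)), label = "square")
#' geodesicMeasures(sq)
#' @export
RangePolygon <- function(coords, label = "", hole = NULL) {
  if (is.data.frame(coords)) coords <- as.matrix(coords[, 1:2])
  if (is.matrix(coords)) coords <- list(coords)
  if (!is.list(coords)) stop("coords must be a matrix or a list of matrices")
  rings <- list()
  for (r in coords) {
    if (is.data.frame(r)) r <- as.matrix(r[, 1:2])
    r <- matrix(as.numeric(r), ncol = 2, dimnames = NULL)
    # drop an explicit closing vertex
    if (nrow(r) >= 2 && all(r[1, ] == r[nrow(r), ])) r <- r[-nrow(r), , drop = FALSE]
    r <- .dropDupVertices(r)
    if (nrow(r) >= 3 && abs(.ringAreaSigned(r)) > 0)
      rings[[length(rings) + 1L]] <- r
  }
  if (is.null(hole)) {
    hole <- .classifyHoles(rings)
  } else {
    hole <- rep_len(as.logical(hole), length(rings))
  }
  # normalise orientation: shells CCW, holes CW (cosmetic; measures use abs)
  for (k in seq_along(rings)) {
    ccw <- .ringAreaSigned(rings[[k]]) > 0
    if (hole[k] == ccw) rings[[k]] <- rings[[k]][rev(seq_len(nrow(rings[[k]]))), , drop = FALSE]
  }
  new("RangePolygon", rings = rings, hole = hole, label = as.character(label)[1])
}

# Even-odd parity: ring k is a hole iff its representative vertex lies inside
# an odd number of the other rings.
.classifyHoles <- function(rings) {
  nR <- length(rings)
  if (nR <= 1) return(rep(FALSE, nR))
  hole <- logical(nR)
  for (k in seq_len(nR)) {
    depth <- 0L
    # a point slightly inside ring k: mean of first vertex and ring centroid
    rk <- rings[[k]]
    probe <- rk[1, ] * 0.999 + colMeans(rk) * 0.001
    for (m in seq_len(nR)) {
      if (m == k) next
      if (.pipRing(probe[1], probe[2], rings[[m]])) depth <- depth + 1L
    }
    hole[k] <- depth %% 2L == 1L
  }
  hole
}

#' Axis-aligned rectangle polygon
#'
#' Convenience constructor for a lon/lat rectangle, used for synthetic
#' regions and simple study areas.
#'
#' @param west,south,east,north rectangle edges in decimal degrees.
#' @param label source tag.
#' @return a [RangePolygon-class] with one CCW ring.
#' @export
rectanglePolygon <- function(west, south, east, north, label = "rectangle") {
  stopifnot(east > west, north > south)
  RangePolygon(cbind(c(west, east, east, west), c(south, south, north, north)),
    label = label)
}

#' @rdname accessors
#' @param x an object of the matching class.
#' @export
setMethod("polygonRings", "RangePolygon", function(x) x@rings)

#' @rdname accessors
#' @export
setMethod("polygonLabel", "RangePolygon", function(x) x@label)

#' @describeIn RangePolygon-class number of rings.
#' @param x a RangePolygon.
#' @export
setMethod("length", "RangePolygon", function(x) length(x@rings))

.isEmptyPolygon <- function(poly) length(poly@rings) == 0

setMethod("show", "RangePolygon", function(object) {
  if (.isEmptyPolygon(object)) {
    cat("RangePolygon (empty)\n")
    return(invisible(NULL))
  }
  m <- geodesicMeasures(object)
  cat(sprintf("RangePolygon '%s': %d ring(s) (%d hole(s)), area %.1f km2, perimeter %.1f km\n",
    object@label, length(object@rings), sum(object@hole),
    m["area_km2"], m["perimeter_km"]))
})

#' @rdname geodesicMeasures
setMethod("geodesicMeasures", "RangePolygon", function(poly) {
  if (.isEmptyPolygon(poly)) stop("empty polygon")
  area <- 0; perim <- 0
  for (k in seq_along(poly@rings)) {
    a <- .ringAreaKm2(poly@rings[[k]])
    area <- area + if (poly@hole[k]) -a else a
    perim <- perim + .ringPerimeterKm(poly@rings[[k]])
  }
  c(area_km2 = area, perimeter_km = perim)
})

#' Map-geometry metrics of an expert range map
#'
#' The three shape descriptors used as map-geometry predictors of the expert
#' score: the Polsby-Popper compactness index 4*pi*A/P^2 (1 for a circle),
#' the convex hull score A / A(convex hull) (1 for a convex map), and the
#' detailed edge A / P in km (small values indicate much boundary detail per
#' unit area).  Areas and perimeters are ellipsoidal (WGS84).
#'
#' @param poly a [RangePolygon-class].
#' @return \code{polsbyPopper}, \code{convexHullScore} and
#'   \code{detailedEdge} return a single number; \code{mapGeometry} returns a
#'   one-row data.frame with all three plus area and perimeter.
#' @examples
#' sq <- rectanglePolygon(0, 0, 1, 1)
#' polsbyPopper(sq)      # ~ pi/4 for a square
#' convexHullScore(sq)   # 1, the square is convex
#' @name mapGeometry
NULL

#' @rdname mapGeometry
setMethod("polsbyPopper", "RangePolygon", function(poly) {
  m <- geodesicMeasures(poly)
  if (m["perimeter_km"] <= 0) stop("zero perimeter")
  pp <- unname(4 * pi * m["area_km2"] / m["perimeter_km"]^2)
  if (pp > 1 && pp < 1 + 1e-9) pp <- 1
  pp
})

#' @rdname mapGeometry
setMethod("convexHullScore", "RangePolygon", function(poly) {
  if (.isEmptyPolygon(poly)) stop("empty polygon")
  m <- geodesicMeasures(poly)
  hull <- .convexHullXY(do.call(rbind, poly@rings))
  hullArea <- .ringAreaKm2(hull)
  score <- unname(m["area_km2"] / hullArea)
  if (score > 1 && score < 1 + 1e-9) score <- 1
  score
})

#' @rdname mapGeometry
setMethod("detailedEdge", "RangePolygon", function(poly) {
  m <- geodesicMeasures(poly)
  if (m["perimeter_km"] <= 0) stop("zero perimeter")
  unname(m["area_km2"] / m["perimeter_km"])
})

#' @rdname mapGeometry
#' @export
mapGeometry <- function(poly) {
  m <- geodesicMeasures(poly)
  data.frame(label = poly@label,
    area_km2 = unname(m["area_km2"]),
    perimeter_km = unname(m["perimeter_km"]),
    polsby_popper = polsbyPopper(poly),
    convex_hull_score = convexHullScore(poly),
    detailed_edge = detailedEdge(poly))
}

#' Convex hull of one or more range polygons and extra points
#'
#' @param ... [RangePolygon-class] objects (empty ones allowed) and/or
#'   2-column coordinate matrices.
#' @param label label for the result.
#' @return a convex [RangePolygon-class].
#' @export
convexHullPolygon <- function(..., label = "convex hull") {
  pts <- matrix(numeric(0), 0, 2)
  for (obj in list(...)) {
    if (is.null(obj)) next
    if (is(obj, "RangePolygon")) {
      if (!.isEmptyPolygon(obj)) pts <- rbind(pts, do.call(rbind, obj@rings))
    } else {
      m <- if (is.data.frame(obj)) as.matrix(obj[, 1:2]) else obj
      if (nrow(m)) pts <- rbind(pts, m)
    }
  }
  if (nrow(pts) < 3) stop("need at least 3 points for a convex hull")
  RangePolygon(.convexHullXY(pts), label = label)
}
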