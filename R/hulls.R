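#' @include RangePolygon.R
NULL

#' Alpha hull of occurrence points
#'
#' Computes the alpha shape of a point set in lon/lat degree space: the union
#' of the Delaunay triangles whose circumradius does not exceed \code{alphaDeg}
#' (a disk radius in decimal degrees).  Unlike the convex hull, the alpha
#' hull can split into disjoint components, separating isolated distant
#' records from the core of the range; as alpha grows it converges to the
#' convex hull.  The computation is a planar approximation in degree space.
#'
#' @param points 2-column matrix or data.frame of lon/lat coordinates.
#' @param alphaDeg disk radius in degrees (default 8).
#' @param label label for the returned polygon.
#' @return a [RangePolygon-class], possibly with several components.  With
#'   fewer than 3 distinct non-collinear points the convex hull of the points
#'   buffered by \code{alphaDeg}/10 is returned with a warning.
#' @examples
#' set.seed(1)
#' pts <- cbind(runif(40, 0, 3), runif(40, 0, 3))
#' alphaHull(pts, alphaDeg = 8)
#' @export
alphaHull <- function(points, alphaDeg = 8, label = "alpha hull") {
  if (is.data.frame(points)) points <- as.matrix(points[, 1:2])
  points <- unique(points[stats::complete.cases(points), , drop = FALSE])
  if (alphaDeg <= 0) stop("alphaDeg must be positive")
  fallback <- function(msg) {
    warning("alpha hull degenerate (", msg, "); falling back to a buffered convex hull")
    d <- alphaDeg / 10
    if (nrow(points) == 1) {
      th <- seq(0, 2 * pi, length.out = 33)[-33]
      return(RangePolygon(cbind(points[1, 1] + d * cos(th),
                                points[1, 2] + d * sin(th)), label = label))
    }
    hull <- .convexHullXY(points)
    if (nrow(hull) < 3 || abs(.ringAreaSigned(hull)) < 1e-12) {
      # two points or a collinear set: thin quadrilateral around the extremes
      ord <- order(points[, 1], points[, 2])
      a <- points[ord[1], ]; b <- points[ord[length(ord)], ]
      dir <- b - a
      nrm <- c(-dir[2], dir[1]) / sqrt(sum(dir^2)) * 1e-6
      hull <- rbind(a - nrm, b - nrm, b + nrm, a + nrm)
    }
    RangePolygon(.bufferConvexRing(hull, d), label = label)
  }
  if (nrow(points) < 3) return(fallback("fewer than 3 distinct points"))
  if (abs(.ringAreaSigned(.convexHullXY(points))) < 1e-12)
    return(fallback("all points collinear"))
  tri <- .alphaTriangles(points, alphaDeg)
  if (nrow(tri) == 0) return(fallback("no triangle with circumradius <= alpha"))
  rings <- .boundaryRingsFromTris(points, tri)
  if (!length(rings)) return(fallback("boundary extraction failed"))
  RangePolygon(rings, label = label)
}

#' Build the study area S for a species
#'
#' Reproduces the study-area construction used for scoring: (1) an alpha hull
#' around the occurrence records removes highly distant isolated points;
#' (2) the convex hull of the union of that alpha hull and the expert maps
#' defines the candidate region; (3) the result is clipped to land.
#'
#' @param occurrences 2-column matrix/data.frame of lon/lat occurrence
#'   records, or NULL.
#' @param mapA,mapB expert range maps ([RangePolygon-class]) or NULL.
#' @param land land-mass boundary to clip against ([RangePolygon-class]), or
#'   NULL to skip clipping.
#' @param alphaDeg alpha-hull disk radius in degrees (default 8).
#' @return a [StudyArea-class]; its provenance records alphaDeg, the number
#'   of occurrence points used and the land label.
#' @examples
#' set.seed(2)
#' pts <- cbind(runif(50, 0, 4), runif(50, 0, 3))
#' sa <- buildStudyArea(pts, mapA = rectanglePolygon(0, 0, 2, 2))
#' boundary(sa)
#' @export
buildStudyArea <- function(occurrences = NULL, mapA = NULL, mapB = NULL,
                           land = NULL, alphaDeg = 8) {
  nonEmpty <- function(p) !is.null(p) && is(p, "RangePolygon") && !.isEmptyPolygon(p)
  nOcc <- if (is.null(occurrences)) 0L else nrow(occurrences)
  if (nOcc == 0 && !nonEmpty(mapA) && !nonEmpty(mapB))
    stop("at least one of occurrences, mapA, mapB must be non-empty")
  ah <- if (nOcc > 0) alphaHull(occurrences, alphaDeg) else NULL
  hull <- convexHullPolygon(ah, mapA, mapB, label = "study area")
  if (nonEmpty(land)) {
    clipRing <- .ringCCW(hull@rings[[1]])
    rings <- list(); hole <- logical(0)
    for (k in seq_along(land@rings)) {
      clipped <- .clipConvex(land@rings[[k]], clipRing)
      if (nrow(clipped) >= 3 && abs(.ringAreaSigned(clipped)) > 1e-12) {
        rings[[length(rings) + 1L]] <- clipped
        hole <- c(hole, land@hole[k])
      }
    }
    if (!length(rings) || sum(ifelse(hole, -1, 1) *
        vapply(rings, function(r) abs(.ringAreaSigned(r)), numeric(1))) <= 0)
      stop("study area off land")
    bnd <- RangePolygon(rings, label = "study area", hole = hole)
  } else {
    bnd <- hull
  }
  new("StudyArea", boundary = bnd,
    provenance = list(alphaDeg = alphaDeg, nOccurrences = nOcc,
      land = if (nonEmpty(land)) land@label else NA_character_))
}

#' @rdname accessors
#' @export
setMethod("boundary", "StudyArea", function(x) x@boundary)

setMethod("show", "StudyArea", function(object) {
  m <- geodesicMeasures(object@boundary)
  cat(sprintf("StudyArea: %.1f km2 (alpha = %s deg, %s occurrence points, land clip: %s)\n",
    m["area_km2"], format(object@provenance$alphaDeg),
    format(object@provenance$nOccurrences), format(object@provenance$land)))
})
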