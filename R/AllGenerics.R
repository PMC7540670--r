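#' @include AllClasses.R
NULL

#' Geodesic area and perimeter of a range polygon
#'
#' Measures a [RangePolygon-class] on the WGS84 ellipsoid: area in km2
#' (holes subtracted) and perimeter in km (holes included).
#'
#' @param poly a [RangePolygon-class].
#' @return named numeric vector with elements \code{area_km2} and
#'   \code{perimeter_km}.
#' @examples
#' sq <- rectanglePolygon(0, 0, 1, 1)
#' geodesicMeasures(sq)
#' @export
setGeneric("geodesicMeasures", function(poly) standardGeneric("geodesicMeasures"))

#' @rdname mapGeometry
#' @export
setGeneric("polsbyPopper", function(poly) standardGeneric("polsbyPopper"))

#' @rdname mapGeometry
#' @export
setGeneric("convexHullScore", function(poly) standardGeneric("convexHullScore"))

#' @rdname mapGeometry
#' @export
setGeneric("detailedEdge", function(poly) standardGeneric("detailedEdge"))

#' Quadrature grid over a study area
#'
#' Builds the graticule-aligned lon/lat grid that partitions the study area
#' into quadrature cells A_j.  The grid origin is snapped to multiples of the
#' resolution; a cell belongs to the study area iff its centre falls inside
#' the boundary (half-open cell intervals break boundary ties).
#'
#' @param x a [StudyArea-class] or bare [RangePolygon-class] boundary.
#' @param resolutionArcmin cell size in arc minutes (default 10).
#' @return a [GridSpec-class].
#' @examples
#' g <- makeGrid(rectanglePolygon(0, 0, 1, 1), 10)
#' sum(gridMask(g))   # 36 cells of 10 arcmin in a 1-degree square
#' @export
setGeneric("makeGrid", function(x, resolutionArcmin = 10) standardGeneric("makeGrid"))

# --- small accessors -------------------------------------------------------

#' @rdname accessors
#' @export
setGeneric("polygonRings", function(x) standardGeneric("polygonRings"))

#' @rdname accessors
#' @export
setGeneric("polygonLabel", function(x) standardGeneric("polygonLabel"))

#' @rdname accessors
#' @export
setGeneric("gridMask", function(x) standardGeneric("gridMask"))

#' @rdname accessors
#' @export
setGeneric("cellAreas", function(x) standardGeneric("cellAreas"))

#' @rdname accessors
#' @export
setGeneric("cellCenters", function(x) standardGeneric("cellCenters"))

#' @rdname accessors
#' @export
setGeneric("boundary", function(x) standardGeneric("boundary"))

#' @rdname accessors
#' @export
setGeneric("occupancy", function(x) standardGeneric("occupancy"))

#' @rdname accessors
#' @export
setGeneric("modelTable", function(x) standardGeneric("modelTable"))

#' @rdname accessors
#' @export
setGeneric("importance", function(x) standardGeneric("importance"))
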