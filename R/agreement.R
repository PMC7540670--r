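#' @include RangePolygon.R
NULL

#' Expert agreement between two range maps
#'
#' Jaccard agreement between two expert maps: the area of their intersection
#' divided by the area of their union, on the WGS84 ellipsoid.  The value
#' scales from 0 (complete disagreement, disjoint maps) to 1 (complete
#' agreement, identical maps).
#'
#' Areas are evaluated in an authalic equal-area projection so that the
#' intersection, computed by planar polygon clipping, and the two map areas
#' are measured consistently; the union is obtained as
#' |A| + |B| - |A intersect B|.
#'
#' @param mapA,mapB [RangePolygon-class] expert maps; at least one must be
#'   non-empty.
#' @return a list with elements \code{agreement},
#'   \code{intersection_area_km2} and \code{union_area_km2}.
#' @examples
#' a <- rectanglePolygon(0, 0, 1, 1)
#' b <- rectanglePolygon(0.5, 0, 1.5, 1)
#' expertAgreement(a, b)$agreement   # 1/3: overlap 0.5, union 1.5
#' @export
expertAgreement <- function(mapA, mapB) {
  emptyA <- .isEmptyPolygon(mapA); emptyB <- .isEmptyPolygon(mapB)
  if (emptyA && emptyB) stop("no ranges to compare")
  areaOf <- function(p) {
    if (.isEmptyPolygon(p)) return(0)
    sum(ifelse(p@hole, -1, 1) * vapply(p@rings, function(r)
      abs(.ringAreaSigned(.projectEqualArea(r))) * .EA_SCALE_KM2, numeric(1)))
  }
  aA <- areaOf(mapA); aB <- areaOf(mapB)
  inter <- if (emptyA || emptyB) 0 else .agreementIntersection(mapA, mapB)
  # guard against clipping round-off
  inter <- min(max(inter, 0), aA, aB)
  union <- aA + aB - inter
  list(agreement = if (union > 0) inter / union else 0,
    intersection_area_km2 = inter, union_area_km2 = union)
}

.agreementIntersection <- function(mapA, mapB) {
  # exact fast path: geometrically identical maps
  if (.samePolygon(mapA, mapB)) {
    return(sum(ifelse(mapA@hole, -1, 1) * vapply(mapA@rings, function(r)
      abs(.ringAreaSigned(.projectEqualArea(r))) * .EA_SCALE_KM2, numeric(1))))
  }
  projA <- lapply(mapA@rings, .projectEqualArea)
  projB <- lapply(mapB@rings, .projectEqualArea)
  bbA <- .bboxRing(do.call(rbind, projA))
  bbB <- .bboxRing(do.call(rbind, projB))
  if (.bboxDisjoint(bbA, bbB)) return(0)
  # convex-convex fast path
  if (length(projA) == 1 && length(projB) == 1 &&
      .isConvexRing(projA[[1]]) && .isConvexRing(projB[[1]])) {
    clp <- .clipConvex(.ringCCW(projA[[1]]), .ringCCW(projB[[1]]))
    if (nrow(clp) < 3) return(0)
    return(abs(.ringAreaSigned(clp)) * .EA_SCALE_KM2)
  }
  .intersectionAreaXY(projA, mapA@hole, projB, mapB@hole) * .EA_SCALE_KM2
}

.samePolygon <- function(a, b) {
  if (length(a@rings) != length(b@rings)) return(FALSE)
  if (!identical(a@hole, b@hole)) return(FALSE)
  for (k in seq_along(a@rings)) {
    ra <- a@rings[[k]]; rb <- b@rings[[k]]
    if (!identical(dim(ra), dim(rb))) return(FALSE)
    # allow cyclic shift of the start vertex
    n <- nrow(ra)
    hit <- FALSE
    starts <- which(rb[, 1] == ra[1, 1] & rb[, 2] == ra[1, 2])
    for (s in starts) {
      idx <- ((s - 1 + seq_len(n) - 1) %% n) + 1
      if (all(ra == rb[idx, , drop = FALSE])) { hit <- TRUE; break }
    }
    if (!hit) return(FALSE)
  }
  TRUE
}
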