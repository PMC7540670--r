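# Internal planar computational-geometry kernel.
#
# All functions here work on bare numeric matrices in an arbitrary planar
# coordinate system (lon/lat degrees for topology-only operations, or the
# equal-area projection from ellipsoid.R when areas must be metric).
# Rings are open (first vertex not repeated) 2-column matrices.

.ringAreaSigned <- function(xy) {
  n <- nrow(xy)
  if (n < 3) return(0)
  x <- xy[, 1]; y <- xy[, 2]
  j <- c(n, seq_len(n - 1))
  sum(x[j] * y - x * y[j]) / 2
}

.ringCCW <- function(xy) if (.ringAreaSigned(xy) < 0) xy[rev(seq_len(nrow(xy))), , drop = FALSE] else xy

.dropDupVertices <- function(xy, tol = 0) {
  n <- nrow(xy)
  if (n < 2) return(xy)
  nxt <- c(seq_len(n)[-1], 1L)
  keep <- !(abs(xy[, 1] - xy[nxt, 1]) <= tol & abs(xy[, 2] - xy[nxt, 2]) <= tol)
  # keep[i] is FALSE when vertex i duplicates its successor
  xy[c(keep[n], keep[-n]), , drop = FALSE]
}

.bboxRing <- function(xy) c(min(xy[, 1]), min(xy[, 2]), max(xy[, 1]), max(xy[, 2]))

.bboxDisjoint <- function(a, b, tol = 0)
  a[3] < b[1] - tol || b[3] < a[1] - tol || a[4] < b[2] - tol || b[4] < a[2] - tol

# Even-odd (crossing number) point-in-ring test, vectorised over points.
.pipRing <- function(px, py, ring) {
  n <- nrow(ring)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    crosses <- ((yi > py) != (yj > py))
    if (any(crosses)) {
      xint <- xi + (py - yi) * (xj - xi) / (yj - yi)
      inside <- xor(inside, crosses & (px < xint))
    }
    j <- i
  }
  inside
}

# Even-odd containment across a set of rings (holes handled by parity).
.pipRings <- function(px, py, rings) {
  inside <- rep(FALSE, length(px))
  for (r in rings) inside <- xor(inside, .pipRing(px, py, r))
  inside
}

.convexHullXY <- function(pts) {
  pts <- unique(pts[stats::complete.cases(pts), , drop = FALSE])
  idx <- grDevices::chull(pts)
  hull <- pts[idx, , drop = FALSE]
  .ringCCW(hull)
}

.isConvexRing <- function(xy, tol = 1e-12) {
  xy <- .dropDupVertices(.ringCCW(xy))
  n <- nrow(xy)
  if (n < 4) return(TRUE)
  scale2 <- max(diff(range(xy[, 1])), diff(range(xy[, 2])))^2
  prv <- c(n, seq_len(n - 1)); nxt <- c(seq_len(n)[-1], 1L)
  cr <- (xy[, 1] - xy[prv, 1]) * (xy[nxt, 2] - xy[, 2]) -
        (xy[, 2] - xy[prv, 2]) * (xy[nxt, 1] - xy[, 1])
  all(cr >= -tol * scale2)
}

# Sutherland-Hodgman: clip an arbitrary subject ring by a convex CCW ring.
# Returns a matrix (possibly 0 rows).  Output can contain zero-width bridges
# when the true intersection is disconnected; areas remain correct.
.clipConvex <- function(subject, clipCCW) {
  out <- subject
  nc <- nrow(clipCCW)
  for (e in seq_len(nc)) {
    if (nrow(out) == 0) return(out)
    a <- clipCCW[e, ]; b <- clipCCW[if (e == nc) 1L else e + 1L, ]
    ex <- b[1] - a[1]; ey <- b[2] - a[2]
    d <- ex * (out[, 2] - a[2]) - ey * (out[, 1] - a[1])  # >0 left (inside)
    n <- nrow(out)
    keepIn <- d >= 0
    res <- matrix(numeric(0), 0, 2)
    prev <- n
    for (i in seq_len(n)) {
      if (keepIn[i]) {
        if (!keepIn[prev]) {
          t <- d[prev] / (d[prev] - d[i])
          res <- rbind(res, out[prev, ] + t * (out[i, ] - out[prev, ]))
        }
        res <- rbind(res, out[i, ])
      } else if (keepIn[prev]) {
        t <- d[prev] / (d[prev] - d[i])
        res <- rbind(res, out[prev, ] + t * (out[i, ] - out[prev, ]))
      }
      prev <- i
    }
    out <- res
  }
  out
}

# Ear-clipping triangulation of a simple ring; returns list of 3x2 matrices.
.triangulateRing <- function(ring) {
  ring <- .dropDupVertices(.ringCCW(ring))
  n <- nrow(ring)
  if (n < 3) return(list())
  scale2 <- max(diff(range(ring[, 1])), diff(range(ring[, 2])))^2
  eps <- 1e-13 * scale2
  idx <- seq_len(n)
  tris <- vector("list", max(n - 2, 0)); nt <- 0L
  crossAt <- function(i) {
    m <- length(idx)
    p <- ring[idx[if (i == 1) m else i - 1], ]
    c0 <- ring[idx[i], ]
    q <- ring[idx[if (i == m) 1 else i + 1], ]
    (c0[1] - p[1]) * (q[2] - c0[2]) - (c0[2] - p[2]) * (q[1] - c0[1])
  }
  inTri <- function(p, a, b, c0) {
    d1 <- (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])
    d2 <- (c0[1] - b[1]) * (p[2] - b[2]) - (c0[2] - b[2]) * (p[1] - b[1])
    d3 <- (a[1] - c0[1]) * (p[2] - c0[2]) - (a[2] - c0[2]) * (p[1] - c0[1])
    d1 > eps && d2 > eps && d3 > eps
  }
  guard <- 0L
  while (length(idx) > 3 && guard < 4L * n * n) {
    m <- length(idx)
    clipped <- FALSE
    best <- 0; bestI <- 0L
    for (i in seq_len(m)) {
      cr <- crossAt(i)
      if (cr > best) { best <- cr; bestI <- i }
      if (cr <= eps) next
      a <- ring[idx[if (i == 1) m else i - 1], ]
      b <- ring[idx[i], ]
      c0 <- ring[idx[if (i == m) 1 else i + 1], ]
      others <- idx[-c(if (i == 1) m else i - 1, i, if (i == m) 1 else i + 1)]
      blocked <- FALSE
      for (o in others) if (inTri(ring[o, ], a, b, c0)) { blocked <- TRUE; break }
      if (!blocked) {
        nt <- nt + 1L
        tris[[nt]] <- rbind(a, b, c0)
        idx <- idx[-i]
        clipped <- TRUE
        break
      }
    }
    if (!clipped) {
      # numerically degenerate ring: clip the most convex vertex regardless
      if (bestI == 0L) bestI <- 1L
      m <- length(idx)
      a <- ring[idx[if (bestI == 1) m else bestI - 1], ]
      b <- ring[idx[bestI], ]
      c0 <- ring[idx[if (bestI == m) 1 else bestI + 1], ]
      nt <- nt + 1L
      tris[[nt]] <- rbind(a, b, c0)
      idx <- idx[-bestI]
    }
    guard <- guard + 1L
  }
  if (length(idx) == 3) {
    nt <- nt + 1L
    tris[[nt]] <- ring[idx, , drop = FALSE]
  }
  tris[seq_len(nt)]
}

# Signed triangle decomposition of a multipolygon: shells +1, holes -1.
.signedTriangles <- function(rings, hole) {
  tris <- list(); signs <- numeric(0)
  for (k in seq_along(rings)) {
    tk <- .triangulateRing(rings[[k]])
    tk <- Filter(function(t) abs(.ringAreaSigned(t)) > 0, tk)
    if (length(tk)) {
      tris <- c(tris, tk)
      signs <- c(signs, rep(if (hole[k]) -1 else 1, length(tk)))
    }
  }
  list(tris = tris, signs = signs)
}

# Area of the intersection of two multipolygons given in one planar frame.
# Indicator calculus: 1_A = sum_i s_i 1_{t_i}, so
# |A n B| = sum_ij s_i s_j |t_i n t_j|, each term a convex-convex clip.
.intersectionAreaXY <- function(ringsA, holeA, ringsB, holeB) {
  A <- .signedTriangles(ringsA, holeA)
  B <- .signedTriangles(ringsB, holeB)
  if (!length(A$tris) || !length(B$tris)) return(0)
  bbA <- lapply(A$tris, .bboxRing)
  bbB <- lapply(B$tris, .bboxRing)
  triB <- lapply(B$tris, .ringCCW)
  total <- 0
  for (i in seq_along(A$tris)) {
    ta <- A$tris[[i]]; ba <- bbA[[i]]; sa <- A$signs[i]
    for (j in seq_along(triB)) {
      if (.bboxDisjoint(ba, bbB[[j]])) next
      clp <- .clipConvex(ta, triB[[j]])
      if (nrow(clp) >= 3) total <- total + sa * B$signs[j] * abs(.ringAreaSigned(clp))
    }
  }
  total
}

# ---------------------------------------------------------------------------
# Delaunay triangulation (Bowyer-Watson) and alpha shapes
# ---------------------------------------------------------------------------

.circumcircle <- function(ax, ay, bx, by, cx, cy) {
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  if (abs(d) < .Machine$double.xmin) return(c(NA, NA, Inf))
  a2 <- ax * ax + ay * ay; b2 <- bx * bx + by * by; c2 <- cx * cx + cy * cy
  ux <- (a2 * (by - cy) + b2 * (cy - ay) + c2 * (ay - by)) / d
  uy <- (a2 * (cx - bx) + b2 * (ax - cx) + c2 * (bx - ax)) / d
  c(ux, uy, (ux - ax)^2 + (uy - ay)^2)
}

# Returns an integer matrix of triangle vertex indices into pts (CCW).
.delaunay <- function(pts) {
  n <- nrow(pts)
  if (n < 3) return(matrix(integer(0), 0, 3))
  rng <- apply(pts, 2, range)
  span <- max(rng[2, ] - rng[1, ], 1e-9)
  cx <- mean(rng[, 1]); cy <- mean(rng[, 2])
  M <- 64 * span
  sup <- rbind(c(cx - 2 * M, cy - M), c(cx + 2 * M, cy - M), c(cx, cy + 2 * M))
  P <- rbind(pts, sup)
  s1 <- n + 1L; s2 <- n + 2L; s3 <- n + 3L
  tri <- list(c(s1, s2, s3))
  cc <- list(.circumcircle(P[s1, 1], P[s1, 2], P[s2, 1], P[s2, 2], P[s3, 1], P[s3, 2]))
  for (ip in seq_len(n)) {
    px <- P[ip, 1]; py <- P[ip, 2]
    bad <- logical(length(tri))
    for (t in seq_along(tri)) {
      cct <- cc[[t]]
      bad[t] <- (px - cct[1])^2 + (py - cct[2])^2 <= cct[3] * (1 + 1e-12)
    }
    badIdx <- which(bad)
    if (!length(badIdx)) next  # should not happen inside the super-triangle
    # cavity boundary: edges of bad triangles not shared by two bad triangles
    edges <- matrix(integer(0), 0, 2)
    for (t in badIdx) {
      v <- tri[[t]]
      edges <- rbind(edges, c(v[1], v[2]), c(v[2], v[3]), c(v[3], v[1]))
    }
    keyFwd <- paste(edges[, 1], edges[, 2])
    keyRev <- paste(edges[, 2], edges[, 1])
    boundary <- edges[!(keyFwd %in% keyRev), , drop = FALSE]
    tri <- tri[!bad]; cc <- cc[!bad]
    for (e in seq_len(nrow(boundary))) {
      v1 <- boundary[e, 1]; v2 <- boundary[e, 2]
      newTri <- c(v1, v2, ip)
      # orient CCW
      ar <- (P[v2, 1] - P[v1, 1]) * (py - P[v1, 2]) - (P[v2, 2] - P[v1, 2]) * (px - P[v1, 1])
      if (ar < 0) newTri <- c(v2, v1, ip)
      tri[[length(tri) + 1L]] <- newTri
      cc[[length(cc) + 1L]] <- .circumcircle(P[newTri[1], 1], P[newTri[1], 2],
        P[newTri[2], 1], P[newTri[2], 2], P[newTri[3], 1], P[newTri[3], 2])
    }
  }
  keep <- vapply(tri, function(v) all(v <= n), logical(1))
  if (!any(keep)) return(matrix(integer(0), 0, 3))
  do.call(rbind, tri[keep])
}

# Alpha complex: Delaunay triangles with circumradius <= alpha.
.alphaTriangles <- function(pts, alpha) {
  tri <- .delaunay(pts)
  if (nrow(tri) == 0) return(tri)
  r <- vapply(seq_len(nrow(tri)), function(i) {
    v <- tri[i, ]
    sqrt(.circumcircle(pts[v[1], 1], pts[v[1], 2], pts[v[2], 1], pts[v[2], 2],
      pts[v[3], 1], pts[v[3], 2])[3])
  }, numeric(1))
  tri[r <= alpha, , drop = FALSE]
}

# Chain the once-used directed edges of a CCW triangle set into rings.
.boundaryRingsFromTris <- function(pts, tri) {
  if (nrow(tri) == 0) return(list())
  edges <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  keyFwd <- paste(edges[, 1], edges[, 2])
  keyRev <- paste(edges[, 2], edges[, 1])
  bnd <- edges[!(keyFwd %in% keyRev), , drop = FALSE]
  if (nrow(bnd) == 0) return(list())
  used <- rep(FALSE, nrow(bnd))
  # index outgoing edges by start vertex
  byStart <- split(seq_len(nrow(bnd)), bnd[, 1])
  rings <- list()
  for (e0 in seq_len(nrow(bnd))) {
    if (used[e0]) next
    ringIdx <- integer(0)
    e <- e0
    repeat {
      used[e] <- TRUE
      ringIdx <- c(ringIdx, bnd[e, 1])
      nxtV <- bnd[e, 2]
      cand <- byStart[[as.character(nxtV)]]
      cand <- cand[!used[cand]]
      if (!length(cand)) break
      e <- cand[1]
    }
    if (length(ringIdx) >= 3)
      rings[[length(rings) + 1L]] <- pts[ringIdx, , drop = FALSE]
  }
  rings
}

# Connected components of a triangle set (shared-edge adjacency).
.triComponents <- function(tri) {
  nt <- nrow(tri)
  comp <- integer(nt)
  edgeKey <- function(a, b) paste(pmin(a, b), pmax(a, b))
  keys <- cbind(edgeKey(tri[, 1], tri[, 2]), edgeKey(tri[, 2], tri[, 3]),
                edgeKey(tri[, 3], tri[, 1]))
  lookup <- split(rep(seq_len(nt), 3), as.vector(keys))
  cur <- 0L
  for (s in seq_len(nt)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    stack <- s
    while (length(stack)) {
      t <- stack[[1]]; stack <- stack[-1]
      if (comp[t] != 0L) next
      comp[t] <- cur
      nb <- unique(unlist(lookup[keys[t, ]]))
      stack <- c(stack, nb[comp[nb] == 0L])
    }
  }
  comp
}

# ---------------------------------------------------------------------------
# Rectilinear cell tracing and buffering
# ---------------------------------------------------------------------------

# occ: logical matrix [nCols, nRows]; returns rings in grid-corner coordinates
# (lon/lat), shells CCW / holes CW by construction (interior kept on the left).
.traceCellRings <- function(occ, west, south, resDeg) {
  nC <- nrow(occ); nR <- ncol(occ)
  at <- function(i, j) i >= 1 && i <= nC && j >= 1 && j <= nR && occ[i, j]
  # directed edges between corner nodes; corner (a,b) = (west + a*res, south + b*res)
  from <- list(); to <- list()
  for (i in seq_len(nC)) for (j in seq_len(nR)) {
    if (!occ[i, j]) next
    if (!at(i, j - 1)) { from[[length(from) + 1L]] <- c(i - 1, j - 1); to[[length(to) + 1L]] <- c(i, j - 1) }
    if (!at(i + 1, j)) { from[[length(from) + 1L]] <- c(i, j - 1);     to[[length(to) + 1L]] <- c(i, j) }
    if (!at(i, j + 1)) { from[[length(from) + 1L]] <- c(i, j);         to[[length(to) + 1L]] <- c(i - 1, j) }
    if (!at(i - 1, j)) { from[[length(from) + 1L]] <- c(i - 1, j);     to[[length(to) + 1L]] <- c(i - 1, j - 1) }
  }
  ne <- length(from)
  if (ne == 0) return(list())
  key <- function(v) sprintf("%d_%d", v[1], v[2])
  fromKey <- vapply(from, key, character(1))
  byStart <- split(seq_len(ne), fromKey)
  used <- rep(FALSE, ne)
  dirOf <- function(e) c(to[[e]][1] - from[[e]][1], to[[e]][2] - from[[e]][2])
  rings <- list()
  for (e0 in seq_len(ne)) {
    if (used[e0]) next
    ring <- list()
    e <- e0
    repeat {
      used[e] <- TRUE
      ring[[length(ring) + 1L]] <- from[[e]]
      nxt <- to[[e]]
      cand <- byStart[[key(nxt)]]
      cand <- cand[!used[cand]]
      if (!length(cand)) break
      if (length(cand) > 1) {
        # at a pinch corner prefer the sharpest left turn to keep rings simple
        d <- dirOf(e)
        turnRank <- vapply(cand, function(ce) {
          dn <- dirOf(ce)
          cr <- d[1] * dn[2] - d[2] * dn[1]   # +1 left, -1 right
          dt <- d[1] * dn[1] + d[2] * dn[2]   # +1 straight, -1 back
          # order: left(2), straight(1), right(0), back(-1)
          if (cr > 0) 2 else if (dt > 0) 1 else if (cr < 0) 0 else -1
        }, numeric(1))
        cand <- cand[which.max(turnRank)]
      }
      e <- cand[1]
    }
    if (length(ring) >= 4) {
      m <- do.call(rbind, ring)
      # collapse collinear runs
      n <- nrow(m)
      prv <- c(n, seq_len(n - 1)); nxt2 <- c(seq_len(n)[-1], 1L)
      cr <- (m[, 1] - m[prv, 1]) * (m[nxt2, 2] - m[, 2]) -
            (m[, 2] - m[prv, 2]) * (m[nxt2, 1] - m[, 1])
      m <- m[cr != 0, , drop = FALSE]
      if (nrow(m) >= 3) {
        coords <- cbind(west + m[, 1] * resDeg, south + m[, 2] * resDeg)
        rings[[length(rings) + 1L]] <- coords
      }
    }
  }
  rings
}

# Minkowski dilation of a convex CCW ring by a disk of radius d (same planar
# units), with nArc segments per full quarter-turn of boundary arc.
.bufferConvexRing <- function(ring, d, nArc = 8) {
  ring <- .dropDupVertices(.ringCCW(ring))
  n <- nrow(ring)
  if (n < 3 || d <= 0) return(ring)
  out <- matrix(numeric(0), 0, 2)
  for (k in seq_len(n)) {
    vPrev <- ring[if (k == 1) n else k - 1, ]
    v <- ring[k, ]
    vNext <- ring[if (k == n) 1 else k + 1, ]
    e1 <- v - vPrev; e2 <- vNext - v
    n1 <- c(e1[2], -e1[1]) / sqrt(sum(e1^2))
    n2 <- c(e2[2], -e2[1]) / sqrt(sum(e2^2))
    a1 <- atan2(n1[2], n1[1]); a2 <- atan2(n2[2], n2[1])
    # around a convex CCW ring the outward normal rotates counterclockwise;
    # sweep from a1 up to a2 through the exterior angle
    while (a2 < a1) a2 <- a2 + 2 * pi
    nSeg <- max(1L, ceiling((a2 - a1) / (pi / 2) * nArc))
    th <- seq(a1, a2, length.out = nSeg + 1)
    out <- rbind(out, cbind(v[1] + d * cos(th), v[2] + d * sin(th)))
  }
  out
}

# Ramer-Douglas-Peucker ring simplification (tolerance in coordinate units).
.rdpSimplify <- function(ring, tol) {
  if (tol <= 0 || nrow(ring) <= 4) return(ring)
  simplifyOpen <- function(pts) {
    n <- nrow(pts)
    if (n <= 2) return(pts)
    a <- pts[1, ]; b <- pts[n, ]
    ab <- b - a; len2 <- sum(ab^2)
    d <- vapply(seq_len(n), function(i) {
      p <- pts[i, ]
      if (len2 == 0) return(sqrt(sum((p - a)^2)))
      abs(ab[1] * (p[2] - a[2]) - ab[2] * (p[1] - a[1])) / sqrt(len2)
    }, numeric(1))
    i <- which.max(d)
    if (d[i] <= tol) return(pts[c(1, n), , drop = FALSE])
    left <- simplifyOpen(pts[1:i, , drop = FALSE])
    right <- simplifyOpen(pts[i:n, , drop = FALSE])
    rbind(left[-nrow(left), , drop = FALSE], right)
  }
  # anchor at the two most distant vertices to keep the ring closed
  closed <- rbind(ring, ring[1, , drop = FALSE])
  half <- ceiling(nrow(ring) / 2)
  p1 <- simplifyOpen(closed[1:half, , drop = FALSE])
  p2 <- simplifyOpen(closed[half:nrow(closed), , drop = FALSE])
  out <- rbind(p1, p2[-1, , drop = FALSE])
  out <- out[-nrow(out), , drop = FALSE]
  .dropDupVertices(out)
}
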