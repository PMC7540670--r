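# Shared fixtures and independent oracles (kept deliberately naive: direct
# per-cell loops and closed forms, no reuse of package internals).

unitSquare <- function(w = 0, s = 0, side = 1)
  rectanglePolygon(w, s, w + side, s + side)

# brute-force quadrature deviance: explicit per-cell loop
bruteDeviance <- function(y, p, w) {
  tot <- 0
  for (j in seq_along(y)) {
    lj <- if (y[j] == 1) -2 * log(p[j]) else -2 * log(1 - p[j])
    tot <- tot + lj * w[j]
  }
  tot
}

# brute-force expert score from per-cell vectors
bruteExpertScore <- function(y, p, w) {
  dExp <- bruteDeviance(y, p, w)
  dNull <- bruteDeviance(rep(1, length(p)), p, w)
  list(score = 1 - dExp / dNull,
    scaledIn = bruteDeviance(y[y == 1], p[y == 1], w[y == 1]) / dNull,
    scaledOut = bruteDeviance(y[y == 0], p[y == 0], w[y == 0]) / dNull)
}

# direct-formula Moran's I with row-standardised weights from a full
# neighbour matrix (O(n^2), independent of the package's pair lists)
bruteMoransI <- function(x, W) {
  n <- length(x)
  rs <- rowSums(W)
  Wn <- W / ifelse(rs == 0, 1, rs)
  z <- x - mean(x)
  (n / sum(Wn)) * sum(Wn * outer(z, z)) / sum(z^2)
}

rookMatrix <- function(nc, nr) {
  n <- nc * nr
  W <- matrix(0, n, n)
  for (i in seq_len(nc)) for (j in seq_len(nr)) {
    a <- (j - 1) * nc + i
    for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      i2 <- i + d[1]; j2 <- j + d[2]
      if (i2 >= 1 && i2 <= nc && j2 >= 1 && j2 <= nr)
        W[a, (j2 - 1) * nc + i2] <- 1
    }
  }
  W
}

# random probability surface on a grid (all cells get finite lambdaBar)
randomSurface <- function(grid, seed) {
  set.seed(seed)
  n <- length(gridMask(grid))
  occupancyProbability(runif(n, 0.01, 3), grid)
}
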