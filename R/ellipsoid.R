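# WGS84 measures: ellipsoidal ring areas/perimeters (via geosphere) and an
# authalic equal-area projection used for planar intersection areas.

.WGS84_A  <- 6378137          # semi-major axis, m
.WGS84_F  <- 1 / 298.257223563
.WGS84_E2 <- .WGS84_F * (2 - .WGS84_F)

# Authalic area function: area between the equator and latitude phi is
# a^2 * dlambda * q(phi) / 2, so y = q(phi)/2 with x = lambda (radians)
# gives an equal-area plane with area scale a^2.
.authalicQ <- function(latDeg) {
  e <- sqrt(.WGS84_E2)
  s <- sin(latDeg * pi / 180)
  (1 - .WGS84_E2) * (s / (1 - .WGS84_E2 * s^2) + atanh(e * s) / e)
}

# Equal-area projection of lon/lat (degrees) to a plane whose shoelace areas,
# multiplied by (a/1000)^2, are ellipsoidal areas in km2.
.projectEqualArea <- function(xy) {
  cbind(xy[, 1] * pi / 180, .authalicQ(xy[, 2]) / 2)
}

.EA_SCALE_KM2 <- (.WGS84_A / 1000)^2

# Ellipsoidal area (km2) of a graticule cell [lonW, lonE] x [latS, latN].
.cellAreaKm2 <- function(latS, latN, dLonDeg) {
  .EA_SCALE_KM2 * (dLonDeg * pi / 180) * (.authalicQ(latN) - .authalicQ(latS)) / 2
}

# Unsigned ellipsoidal area of one ring, km2 (geosphere, Karney-style path).
.ringAreaKm2 <- function(ring) {
  abs(geosphere::areaPolygon(ring)) / 1e6
}

# Ellipsoidal perimeter of one ring, km.
.ringPerimeterKm <- function(ring) {
  closed <- rbind(ring, ring[1, , drop = FALSE])
  sum(geosphere::distGeo(closed[-nrow(closed), , drop = FALSE],
                         closed[-1, , drop = FALSE])) / 1000
}
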