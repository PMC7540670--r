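# Geodesic map-geometry metrics: area/perimeter, Polsby-Popper, convex hull
# score, detailed edge.

test_that("geodesic area and perimeter match ellipsoidal closed forms", {
  sq <- unitSquare()
  m <- geodesicMeasures(sq)
  # spherical-excess oracle on the authalic sphere, frozen before the build
  expect_lt(abs(m["area_km2"] - 12364) / 12364, 0.01)
  # 4 sides of ~111 km
  expect_lt(abs(m["perimeter_km"] - 443.8), 0.5)

  # orientation-insensitive
  rev_sq <- RangePolygon(sq@rings[[1]][4:1, ])
  expect_equal(geodesicMeasures(rev_sq), m)

  # a hole equal to the shell annihilates the area
  degen <- RangePolygon(list(sq@rings[[1]], sq@rings[[1]]),
    hole = c(FALSE, TRUE))
  expect_equal(unname(geodesicMeasures(degen)["area_km2"]), 0)

  # empty geometry errors
  empty <- new("RangePolygon", rings = list(), hole = logical(0), label = "")
  expect_error(geodesicMeasures(empty), "empty")
})

test_that("holes subtract area and add perimeter", {
  outer <- cbind(c(0, 3, 3, 0), c(0, 0, 3, 3))
  inner <- cbind(c(1, 2, 2, 1), c(1, 1, 2, 2))
  holed <- RangePolygon(list(outer, inner))
  expect_true(holed@hole[2])
  full <- RangePolygon(outer)
  hole <- RangePolygon(inner)
  mh <- geodesicMeasures(holed)
  expect_equal(unname(mh["area_km2"]),
    unname(geodesicMeasures(full)["area_km2"] - geodesicMeasures(hole)["area_km2"]),
    tolerance = 1e-10)
  expect_equal(unname(mh["perimeter_km"]),
    unname(geodesicMeasures(full)["perimeter_km"] + geodesicMeasures(hole)["perimeter_km"]),
    tolerance = 1e-10)
})

test_that("Polsby-Popper hits its closed forms", {
  # geodesic circle: the isoperimetric optimum
  th <- seq(0, 359, by = 3)
  circ <- RangePolygon(geosphere::destPoint(c(0, 0), th, 11000))
  expect_equal(polsbyPopper(circ), 1, tolerance = 1e-3)

  expect_equal(polsbyPopper(unitSquare()), pi / 4, tolerance = 1e-3)

  # 10:1 rectangle with sides in a true metric ratio
  latSideKm <- geosphere::distGeo(c(0, 0), c(0, 0.1)) / 1000
  lonExtent <- 10 * latSideKm / (geosphere::distGeo(c(0, 0.05), c(1, 0.05)) / 1000)
  thin <- rectanglePolygon(0, 0, lonExtent, 0.1)
  expect_equal(polsbyPopper(thin), 4 * pi * 10 / 22^2, tolerance = 1e-3)

  empty <- new("RangePolygon", rings = list(), hole = logical(0), label = "")
  expect_error(polsbyPopper(empty), "empty")
})

test_that("convex hull score matches planar small-polygon oracles", {
  expect_equal(convexHullScore(unitSquare()), 1, tolerance = 1e-9)

  # L-shape: unit square minus upper-right quadrant; hull area 7/8
  L <- RangePolygon(cbind(c(0, 1, 1, 0.5, 0.5, 0), c(0, 0, 0.5, 0.5, 1, 1)))
  expect_equal(convexHullScore(L), 0.75 / 0.875, tolerance = 1e-3)

  # two disjoint unit squares 3 degrees apart: hull is a 5 x 1 strip
  two <- RangePolygon(list(unitSquare()@rings[[1]], unitSquare(4)@rings[[1]]))
  expect_equal(convexHullScore(two), 2 / 5, tolerance = 1e-3)
  expect_lt(convexHullScore(two), 0.5)
})

test_that("detailed edge is area over perimeter in km", {
  sq <- unitSquare()
  m <- geodesicMeasures(sq)
  expect_equal(detailedEdge(sq), unname(m["area_km2"] / m["perimeter_km"]))
  # ~ side/4 for a square
  expect_lt(abs(detailedEdge(sq) - m["perimeter_km"] / 16) / detailedEdge(sq), 0.01)

  # circle: r/2
  circ <- RangePolygon(geosphere::destPoint(c(0, 40), seq(0, 359, 2), 100000))
  expect_equal(detailedEdge(circ), 50, tolerance = 0.5)

  # boundary detail lowers the ratio at equal area: cross vs same-area square
  cross <- RangePolygon(cbind(
    c(1, 2, 2, 3, 3, 2, 2, 1, 1, 0, 0, 1) / 3,
    c(0, 0, 1, 1, 2, 2, 3, 3, 2, 2, 1, 1) / 3))
  sqEq <- rectanglePolygon(0, 0, sqrt(5) / 3, sqrt(5) / 3)
  expect_equal(unname(geodesicMeasures(cross)["area_km2"]),
    unname(geodesicMeasures(sqEq)["area_km2"]), tolerance = 1e-3)
  expect_lt(detailedEdge(cross), detailedEdge(sqEq))
})

test_that("shape metrics are invariant under translation along the equator", {
  L <- RangePolygon(cbind(c(0, 1, 1, 0.5, 0.5, 0), c(0, 0, 0.5, 0.5, 1, 1)))
  Lt <- RangePolygon(cbind(c(0, 1, 1, 0.5, 0.5, 0) + 40, c(0, 0, 0.5, 0.5, 1, 1)))
  expect_equal(polsbyPopper(L), polsbyPopper(Lt), tolerance = 1e-3)
  expect_equal(convexHullScore(L), convexHullScore(Lt), tolerance = 1e-3)
})

test_that("mapGeometry returns the predictor row", {
  row <- mapGeometry(unitSquare())
  expect_named(row, c("label", "area_km2", "perimeter_km", "polsby_popper",
    "convex_hull_score", "detailed_edge"))
  expect_equal(row$convex_hull_score, 1, tolerance = 1e-9)
})

test_that("antimeridian-spanning rings are rejected", {
  expect_error(RangePolygon(cbind(c(-170, 170, 170, -170), c(0, 0, 5, 5))),
    "antimeridian")
})
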