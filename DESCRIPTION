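Package: rangescore
Title: Proper Scoring of Expert Range Maps Against Species Distribution
    Model Surfaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Evaluates binary expert range maps against continuous
    occupancy-probability surfaces derived from inhomogeneous Poisson
    point-process (IPP) species distribution models. Implements the
    Bernoulli proper scoring rule, quadrature deviance on a geodesic
    lon/lat grid, the null-map-normalised expert score with its
    commission (inside) and omission (outside) decomposition, geodesic
    map-geometry metrics (Polsby-Popper index, convex hull score,
    detailed edge), Jaccard expert agreement between maps, alpha-hull
    based study-area construction, log-linear IPP intensity fitting,
    Moran's I occurrence statistics, and exhaustive AICc multimodel
    inference with Akaike-weight predictor importance. A seeded
    synthetic-scenario generator produces intensity surfaces, point
    patterns and stylised expert maps so the full pipeline runs without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    geosphere,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'RangePolygon.R'
    'agreement.R'
    'hulls.R'
    'grid.R'
    'scoring.R'
    'ipp.R'
    'inference.R'
    'synthetic.R'
    'io.R'
    'cli.R'
    'ellipsoid.R'
    'planar.R'
    'rangescore-package.R'
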