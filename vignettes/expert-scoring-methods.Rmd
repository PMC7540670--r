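---
title: "Scoring expert range maps against IPP occupancy surfaces: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring expert range maps against IPP occupancy surfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rangescore)
```

# The problem

Expert-drawn range maps declare a binary occupancy state over continuous
geographic space: inside the polygon the species is asserted present,
outside absent.  Species distribution models (SDMs) built from occurrence
records instead produce a continuous occupancy-probability surface.
`rangescore` quantifies how well a binary expert map agrees with such a
surface, treating the SDM not as truth but as a neutral arbiter, and it
rewards both the *exclusion of unsuitable* area and the *inclusion of
suitable* area.  The same machinery compares two expert maps directly
(Jaccard agreement) and asks which properties of maps, occurrence data and
species traits predict good agreement.

# The model

## Occupancy probability from a point process

Occurrence records are modelled as an inhomogeneous Poisson point process
(IPP) with intensity $\lambda(s) > 0$ (points per km^2^), log-linear in
location-specific covariates:

$$\log \lambda(s) = \beta_0 + \textstyle\sum_k \beta_k x_k(s).$$

Counts in disjoint regions are independent Poisson variables with mean
$\bar\lambda = \int_A \lambda(s)\,ds$, so the probability that a small area
$A$ is occupied at all is

$$p = 1 - e^{-\bar\lambda}.$$

This is the bridge between the point-process SDM and the binary world of
the expert map: every quadrature cell gets an integrated intensity
$\bar\lambda_j$ and hence an occupancy probability $p_j$.

The likelihood is maximised on a Berman–Turner quadrature: the fit
maximises $\sum_i \log\lambda(s_i) - \sum_j \lambda(c_j)\,a_j$, where $s_i$
are the observed points, $c_j$ the masked cell centres and $a_j$ the
ellipsoidal cell areas.  For any model containing an intercept the score
equations force $\sum_j \hat\lambda(c_j)\,a_j = n$: the fitted process
reproduces the observed number of points exactly, which the tests use as a
strong internal check.

## The scoring rule and the deviance

The accuracy of a binary statement $y \in \{0, 1\}$ against a probability
$p$ is measured with twice the Bernoulli negative log-likelihood,

$$l(y, p) = -2\left[y \log p + (1 - y)\log(1 - p)\right],$$

a *proper* scoring rule: its expectation is minimised when the stated
probability equals the true one.  This is the reason AUC is not used as
the primary metric here — AUC can be improved by distorting probabilities
away from the truth, and the package offers no AUC-based acceptance
surface.

The map's deviance over the study area $S$ is the quadrature integral

$$D = \sum_{j \in S} l(y_j, p_j)\, a_j,$$

with $y_j$ the rasterized map state of cell $j$ (cell-centre membership)
and $a_j$ the ellipsoidal cell area acting as quadrature weight.

## Expert score and its decomposition

Deviance alone has no scale, so it is normalised by the deviance of the
*null map* $z(s) \equiv 1$ that covers all of $S$:

$$\text{expert score} = 1 - \frac{D_\text{expert}}{D_\text{null}}.$$

This reads like a deviance-explained coefficient: 1 for a perfect match,
exactly 0 for the null map itself (both deviances are then the same sum,
so the zero is exact in floating point as well), negative when the map
predicts worse than covering everything.  Splitting $S$ into the area $I$
inside the map and $O$ outside it decomposes the deviance exactly:

$$D_\text{expert} = D_I + D_O, \qquad
\text{score} = 1 - \left(\underbrace{D_I / D_\text{null}}_{\text{commission}}
+ \underbrace{D_O / D_\text{null}}_{\text{omission}}\right).$$

Commission (scaled-inside) grows when the map includes unsuitable cells;
omission (scaled-outside) grows when suitable cells are left out.  The
identity `score == 1 - (scaledInside + scaledOutside)` is asserted to
1e-12 across randomized fixtures in the test suite.

## Agreement and map geometry

Two maps are compared by the Jaccard index, intersection area over union
area, on the WGS84 ellipsoid.  Map shape enters the inference stage
through three geometry predictors: the Polsby–Popper compactness
$4\pi A/P^2$, the convex hull score $A/A_\text{hull}$, and the detailed
edge $A/P$ (km).  All areas and perimeters are ellipsoidal.

## Multimodel inference

Predictors are screened in groups by exhaustive main-effects enumeration:
all $2^p - 1$ non-empty subsets are fitted by OLS, ranked by the
small-sample Akaike criterion

$$\mathrm{AICc} = n \log(\mathrm{RSS}/n) + 2k + \frac{2k(k+1)}{n-k-1},$$

with $k$ counting the coefficients plus the residual variance, converted
to Akaike weights $w_m \propto e^{-\Delta_m/2}$ normalised to 1.  A
predictor is *important* when the summed weight of the models containing
it reaches 0.8, and the model refitted on exactly the important predictors
is reported with its adjusted R^2^.

# Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `resolutionArcmin` | 10 | arc minutes | quadrature cell size; the score is grid-dependent only through discretization error |
| `alphaDeg` | 8 | degrees | alpha-hull disk radius for study-area construction; larger values approach the convex hull |
| `clampEps` | 1e-10 | – | probability clamp keeping $l(y,p)$ finite at $p \in \{0,1\}$ |
| `threshold` (importance) | 0.8 | – | summed-weight cutoff for declaring a predictor important |
| map style `threshold` | 0.5 / 0.05 | – | occupancy probability at which synthetic tight / generous maps include a cell |
| map style `dilationDeg` | 0 / 1 | degrees | convex dilation of the generous style |

# Numerical choices

* **Quadrature weights.** Cell areas $a_j$ by default.  Because the score
  is a ratio of two sums over the same grid, any uniform rescaling of the
  weights cancels; weighted and unweighted sums differ only when cell
  areas differ across latitude, and both are available in
  `totalDeviance()`/`expertScore()` via the `weights` argument.
* **Integrated intensity.** $\bar\lambda_j = \lambda(c_j)\,a_j$ (midpoint
  rule), sharing the scoring grid so that fitting and scoring use one
  discretization.
* **Rasterization and ties.** A cell belongs to a polygon iff its centre
  does; cell intervals are half-open ($[w, e) \times [s, n)$), so a point
  on a shared edge belongs to exactly one cell.  No fractional coverage is
  used: each cell carries a single binary $y_j$.
* **Ellipsoidal measure.** Ring areas and perimeters use WGS84 geodesics
  (`geosphere`); graticule cell areas use the closed-form authalic band
  formula, which agrees with the geodesic polygon area to well under 0.1%.
* **Planar operations.** Polygon intersections (for agreement), clipping
  (study area to land), convex hulls, alpha shapes and buffers are
  computed in planar coordinate space: topology in lon/lat degrees,
  intersection *areas* in an authalic equal-area projection so that
  planar shoelace areas are ellipsoidal areas.  Intersections of
  multipolygons use a signed-triangle decomposition (shells positive,
  holes negative) with convex–convex clipping per triangle pair, which is
  exact for valid inputs.  Self-intersecting rings are not repaired
  beyond duplicate-vertex removal and zero-area-ring dropping, and rings
  spanning the antimeridian are rejected outright (none occur in
  contiguous-US-style data; extending support was judged out of scope).
* **Optimisation.** The IPP log-likelihood is concave, so the fit uses
  Newton–Raphson with analytic gradient and Hessian and step halving,
  covariates standardised internally; convergence is declared at gradient
  max-norm 1e-8 (500 iteration cap).  Coefficients and their covariance
  are back-transformed to the original covariate scale.
* **Degenerate inputs.** Empty polygons, zero perimeters, all-certain
  surfaces (null deviance numerically zero), constant Moran fields,
  points outside the mask and rank-deficient OLS designs all raise
  informative errors (or drop the offending model with renormalised
  weights, for the OLS case).

# Design choices on genuinely open points

* **Moran's I neighbours.** Rook contiguity on the scoring grid with
  row-standardised weights (queen available).  Row-standardisation makes
  the checkerboard value exactly −1 and the permutation-null mean
  $-1/(n-1)$, both tested.
* **Alpha-shape parameterisation.** The alpha parameter is a disk
  (circumradius) bound of 8 degrees in lon/lat space, the convention of
  the R alpha-hull tradition; it is a planar approximation in degree
  space, adequate at mid-latitudes where a degree of longitude and
  latitude differ by less than a factor 1.4.
* **Candidate set.** The intercept-only model is excluded, which is what
  makes 3 predictors yield exactly 7 candidate models.
* **Within-group weighting.** Akaike weights are normalised within each
  predictor group; combined models pool the per-group selections into one
  refitted OLS model.
* **Adjusted R^2^.** Reported raw and truncated at zero (negative adjusted
  R^2^ is meaningful for model comparison but reads awkwardly in summary
  tables).
* **I/O dialects.** Polygons as GeoJSON (RFC 7946, EPSG:4326 implied),
  surfaces as long-format CSV (`lon,lat,lambda_bar,p`), occurrences and
  predictor tables as CSV, reports as JSON with the run configuration
  echoed for provenance.

# What the synthetic generator emulates — and what it does not

`makeScenario()` builds a rectangular mid-latitude region (10° × 8° by
default) holding a patchy suitability landscape: a near-zero background
(2e-5 points/km^2^) plus 6 Gaussian kernels with amplitudes 0.01–0.03
points/km^2^ and length scales 0.3–0.8°, chosen so that occupancy
probability approaches 1 in patch cores at a 10-arcmin grid and stays
near 0 between patches.  From the resulting surface two stylised expert
maps are drawn:

* **tight** — cells with $p \ge 0.5$, polygonised with their boundary
  detail kept.  This emulates maps restricted to areas of reliable
  occupancy (high concavity, detailed edge).
* **generous** — cells with $p \ge 0.05$, convexified and dilated by 1°.
  This emulates maps that sweep in every area the species reaches
  (compact, convex, large).

Across seeded scenarios the tight style attains the higher expert score
and the generous deficit loads almost entirely on the commission
component while its omission stays near zero — the qualitative pattern
expected when a generous map encloses large unsuitable gaps.  The test
suite asserts the direction (tight wins in at least 80% of 20 scenarios,
generous omission below 0.05), not any particular published percentage.

The generator deliberately omits several features of real data: observer
and roadside sampling bias, spatially correlated detection effort,
taxonomic noise, truncation of ranges by political boundaries, and map
digitization error.  Passing tests therefore demonstrate correctness of
the machinery and the direction of the style effect under ideal IPP
sampling, not performance of real expert maps against real SDMs.  The
IPP intensity here is log-linear; the scoring side accepts any
externally supplied surface (`readSurfaceCSV()`), so probability surfaces
from tree ensembles or other SDMs can be scored unchanged.

# Problem sizes used in the checks

The packaged checks run on deliberately small instances: quadrature grids
between 8 and 2,880 cells, point patterns of roughly 100–3,500 points,
50 IPP replicates for coverage, 20 scenarios for the style comparison and
1,000 permutations for the Moran null — sizes chosen so the whole suite
completes in well under a minute while keeping every Monte-Carlo margin
at three standard errors or better.

# Known limitations

* Planar clipping can produce zero-width bridge artefacts when a convex
  clip splits a land polygon into several components; areas remain
  correct but component counts are not meaningful (component counting of
  published maps is explicitly out of scope).
* The alpha-shape boundary walker prefers the sharpest left turn at pinch
  vertices; pathological point sets with many cocircular points may still
  produce touching rings.
* Buffering is implemented for convex rings only (it is used after
  convexification); dilating a non-convex map is refused with a warning.
* No reprojection: all inputs must be lon/lat WGS84; antimeridian-spanning
  ranges are rejected.
* The "restrict models to highly probable regions" refinement sometimes
  applied when fitting production SDMs is not implemented; covariate
  choice is entirely the user's.
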