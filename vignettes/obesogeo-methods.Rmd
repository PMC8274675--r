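---
title: "Methods: geohash-aggregated behavior and environment analysis"
author: "obesogeo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: geohash-aggregated behavior and environment analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(obesogeo)
```

## The problem

Childhood obesity prevention programs increasingly want *objective*,
*localized* evidence: where in a city are children physically active,
how often do their trips include fast-food or sports-facility
contacts, and do those behaviors track the availability of such places
near schools? obesogeo implements the analytical chain for that kind of
monitoring: raw per-child GPS fixes with step counts go in; what comes
out are spatially aggregated, privacy-suppressed behavioral indicators,
environment descriptors of the same spatial units, behavior-environment
correlations restricted to school-proximal areas, and before/after
comparisons of a behavior at municipality level.

Because the cohorts such systems run on cannot be redistributed, the
package ships a synthetic-city simulator whose couplings are known, so
every stage can be validated against ground truth.

## Spatial structure: geohashes

All aggregation happens on geohash cells: the standard public base-32
geohash (longitude bit first). A 6-character cell measures roughly
1.22 km x 610 m at the equator and a 7-character cell roughly
153 m x 153 m; widths shrink with the cosine of latitude. The package
works at precision 7 by default (precision 6 is supported). Cell
membership at an edge is decided by the encoding itself: the bisection
places a point on a dividing meridian or parallel into the upper half,
so every point belongs to exactly one cell and per-cell counts are
additive across the 32 precision-(k+1) children of a precision-k cell.

Geometry uses a spherical Earth with R = 6 371 000 m; cell width is
measured along the cell's mid-latitude parallel. At the 153-m scale the
spherical approximation is far below any other error source.

## From fixes to visits

A *fix* is `(child_id, timestamp, lat, lon, steps)`, with `steps` the
increment since the child's previous fix. A *visit* is a maximal run of
consecutive fixes of one child encoding to one cell. Two rules shape
segmentation:

* **Gap rule** (`max_gap_min`, default 5): a gap longer than this ends
  the visit even within one cell. Without it, sparse sampling would
  fabricate arbitrarily long stays.
* **Duration filter** (`min_visit_min`, default 1): candidate runs
  shorter than one minute are dropped; percentages of visits to
  sports-type places use a 10-minute eligibility filter instead
  (`min_sport_visit_min`).

A fix's step increment belongs to the interval that *ends* at the fix,
so the entry fix of a visit contributes no steps to it; visit duration
is exit minus entry time. Days are UTC calendar days by default with a
configurable offset; the simulator emits a single timezone without DST
precisely because real multi-city deployments leave local-time handling
ambiguous.

POI *contacts* are detected by proximity: the time a visit's fixes
spend within `poi_contact_radius_m` (50 m) of a POI is accumulated, and
a contact is counted when it reaches `poi_dwell_min` (1 min). Real
deployments might instead use polygon entry or self-report; proximity
dwell is the stand-in, and both parameters are configurable.

*Residence* is the cell holding the most nighttime (00:00-06:00)
recorded minutes, crediting an inter-fix interval only when both
endpoint fixes lie in the same cell, with ties broken toward the
lexicographically smaller code. Children without nighttime data are
excluded from resident-based indicators.

## Indicators and aggregation bases

Three bases are kept strictly apart and tagged on every output row:

* **visits** - the unweighted mean over all stays; repeat visits by one
  child each count.
* **visitors** - each child's visits to the cell are pooled first
  (total steps over total time), then children are averaged.
* **residents** - a child's daily steps anywhere on the map, averaged
  over days with more than 60 recorded minutes, attributed to the home
  cell. This deliberately measures the people of a place rather than
  the place, mitigating the residential fallacy.

The bases genuinely differ: for one child with visits of 60 steps/60
min and 10 steps/2 min, the visits basis gives mean(60, 300) = 180
steps/h while the visitors basis gives 70/(62/60) ≈ 67.7 steps/h. The
test suite asserts both values exactly.

A cell value is published only when **more than 5** contributions exist
on the row's own basis (6 visits, 6 unique visitors, or 6 residents) -
a small-cell privacy suppression rule, read strictly. The count basis
for the threshold follows the value's own basis because the rows are
independently published quantities.

## Environment characteristics

Per cell and POI category: the plain count of POIs in the cell; a
grid-based density (a 30-m lattice anchored at the cell's southwest
corner - the pitch is standard, the anchor is our choice since none is
canonical - counting POIs within 100 m of each lattice point, averaged
over the lattice; POIs *outside* the cell but within the radius count,
since the definition is a radius, not a clip); and **Food** / **Sports**
composites, the sum of the cell's per-category counts mapped to each
group. The default mapping sends fast food/takeaway, restaurants and
supermarkets/grocery stores to Food, and athletics/sports facilities,
indoor recreation facilities and public parks to Sports; it is a config
file, because category vocabularies differ across POI providers and
countries. Degree conversions use 111 320 m per degree latitude scaled
by cos(latitude) for longitude; at 153-m scale the sub-meter error is
irrelevant.

## Associations near schools

The unit of analysis is the precision-7 cell whose center lies
**strictly** within 1000 m of at least one school. For each configured
(behavior, characteristic) pair the suppressed indicator table is
joined to the environment table on those cells and the Pearson
correlation computed:

r = cov(X, Y) / (sd(X) sd(Y)),

with the sample (n-1) covariance (immaterial to r; fixed for
reproducibility), a two-sided p-value from t = r sqrt((n-2)/(1-r^2))
on n-2 degrees of freedom, and a 95% CI from the Fisher z-transform
tanh(atanh(r) ± z* / sqrt(n-3)). The analysis is stratified by city -
pooling cities with different baselines manufactures spurious
correlations, and a constructed Simpson-style example in the tests
shows the stratified path returning the within-city signs. Raw
per-pair p-values are reported by default; a Benjamini-Hochberg option
exists but is off, matching how such dashboards present exploratory
pairs. Degenerate pairs (fewer than 3 joined cells, zero variance) are
flagged in the output rather than dropped.

The default pairing sends step rates (both bases) to the Food and
Sports composites and each visit-percentage indicator to the count of
its own place type; the food-related percentage pairs with the Food
composite since "food places" spans all food categories.

## Before/after comparison

For two non-overlapping periods (period membership decided by the
visit's *entry* timestamp), the per-cell step rate is computed within
each period and cells are assigned to municipalities by their center
point; a center on a shared border goes to the first municipality in
config order, so no cell is double counted. Here the support rule is
**at least one user per cell** - this analysis deliberately trades the
dashboard's suppression threshold for coverage, and both thresholds
remain independent parameters. Municipality means are unweighted means
over cells; with per-cell values as the samples, the before/after
difference is tested with **Welch's** unequal-variance t test
(Welch-Satterthwaite degrees of freedom). Plain "two-sample t test"
leaves the variance assumption open; Welch is the safer default and a
pooled-variance switch exists. A Total row pools all cells.

## The simulator

`sim_config()` / `simulate_study()` generate a city and cohort with
known couplings:

* POIs per category from an inhomogeneous Poisson process (Gaussian
  downtown peak, via thinning), municipalities as a rectangular
  partition, schools uniform or one per municipality center.
* Each child gets a home (uniform), the nearest school, and a lognormal
  activity multiplier. A day is home -> school -> three after-school
  wander stops within 600 m of school -> home, with straight-line
  walking between anchors at 1.3 m/s - adequate for visit and step
  logic, which never sees road geometry.
* At each wander stop the child makes a food (else sports) POI stop
  with probability `plogis(alpha + beta * z)`, where z is the
  city-standardized POI density of the stop's cell; a POI stop
  relocates the dwell to a POI of that cell. `beta_food = 2` is the
  reference coupling; `beta = 0` removes the density dependence.
* Step increments are Poisson with context rates (home 0.25x, school
  0.6x, walking 10x, dwell 3x of the 400 steps/h baseline); after-period
  days multiply the child's rate by the `activity_shift_after` factor
  of the child's home municipality. Fixes get 3-m GPS jitter, 60-s
  sampling and 10% dropout.

Defaults (200 children, 14 days, ~7 x 7 km city) are the reference
conditions for recovery experiments. The simulator reproduces the
features the pipeline's logic depends on - anchored daily routines,
density-coupled place visits, context-dependent step rates, missing
data - but not realistic human-mobility statistics (no road network,
no heavy-tailed trip lengths, no weekday/weekend structure, no
inter-child contact). Passing recovery tests therefore validates the
*pipeline's inference machinery*, not any claim about real cohorts.

### Validation experiments (what the tests compute)

* **Type-I calibration.** 200 replicate cohorts of 30 children x 2
  days with `beta = 0` *and POI stops disabled* (`alpha = -20`), so the
  measured step rates are generated independently of the food
  environment; the tests assert the fraction of association p-values
  below 0.05 stays within 0.05 ± 0.02. POI stops must be disabled for
  an exact null: a physically simulated contact process cannot be made
  density-independent, because contacts require a place to exist in the
  cell and relocate time there, which couples the context mix of a cell
  to its POI content regardless of beta.
* **Association recovery.** One cohort at the reference conditions
  (200 children, 14 days, `beta_food = 2`): the tests assert the
  %food-visits x Food-composite correlation over school-proximal,
  suppression-filtered cells is positive with p < 0.05.
* **Shift recovery.** 50 seeds of 40 children x (3 + 3) days, four
  municipalities with a school at each center, after-period step-rate
  factor 0.5 in one municipality: the tests assert detection (p < 0.05
  with a negative change) in more than 80% of seeds and a false-positive
  fraction of at most 0.15 across the unshifted municipalities.

These problem sizes are the package's reference validation conditions;
they keep the full suite in the minutes range while leaving each
experiment comfortably powered.

## Numerical and degenerate-input choices

* Pearson r is clamped to [-1, 1] against rounding; |r| = 1 yields
  p = 0 and no Fisher CI (it needs n > 3 and |r| < 1).
* Zero-variance inputs and n < 3 are errors at the statistic level and
  flagged rows at the report level.
* Suppression is idempotent and order-preserving; suppressed row counts
  are reported in the run manifest so accounting always reconciles.
* Day summaries cap each inter-fix interval at the gap limit, so
  outages never count as wear time.
* Empty inputs produce empty, correctly-typed outputs everywhere.

## Known limitations

* Step extraction from raw accelerometry is out of scope; the package
  consumes per-fix step increments.
* Proximity-dwell POI contacts cannot distinguish "walked past slowly"
  from "went inside".
* Associations are correlational; no confounder adjustment or spatial
  autocorrelation modelling is attempted, and geohash cells are
  arbitrary administrative units (the modifiable areal unit problem
  applies).
* The simulator's mobility is deliberately schematic; quantitative
  agreement with any real cohort is not a goal.
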