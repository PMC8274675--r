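# obesogeo

Geohash-aggregated obesogenic-behavior analysis for child mobility
cohorts.

Public-health teams monitoring childhood obesity want objective,
localized answers: where are children physically active, how often do
their trips include fast-food or sports-facility contacts, and do those
behaviors track the availability of such places near schools? obesogeo
turns timestamped GPS + step-count trajectories of a cohort into that
evidence while never exposing individual movement data:

* **Geohash aggregation** — all outputs are per spatial cell (precision
  6: ~1.22 km × 610 m at the equator; precision 7: ~153 m × 153 m),
  published only when **more than 5** contributions exist (privacy
  suppression).
* **Behavioral indicators** — average steps/hour across *visits*
  (repeats counted) and across unique *visitors* (pooled per child);
  percentages of visits including a food- or sports-place contact
  (1-minute visit eligibility for food, 10-minute for sports); average
  daily steps of *residents* (days with >60 recorded minutes),
  attributed to the home cell.
* **Environment characteristics** — per-cell POI counts, a 30-m-grid /
  100-m-radius density, and Food/Sports composites (sums of the
  group's per-category counts).
* **Associations near schools** — Pearson correlation
  r = cov(X,Y)/(σ_X σ_Y) between behavior and environment over the
  precision-7 cells whose centers lie <1000 m from a school, stratified
  by city, with t-based two-sided p-values (df = n−2) and 95% Fisher-z
  confidence intervals tanh(atanh r ± z*/√(n−3)).
* **Before/after comparison** — a behavior aggregated per municipality
  (cells with ≥1 user) in two periods, tested with Welch's
  unequal-variance t test; one row per municipality plus a pooled
  Total row.
* **A synthetic-city simulator** — POIs, schools, municipalities and
  cohort trajectories with configurable density→behavior couplings and
  per-municipality intervention shifts, so every stage can be validated
  against ground truth.

## Worked example

```r
library(obesogeo)

cfg <- sim_config(seed = 42, n_children = 40, n_days = 3,
                  bbox = c(lat_min = 40.60, lat_max = 40.64,
                           lon_min = 22.92, lon_max = 22.97),
                  n_schools = 2)
sim <- simulate_study(cfg)

ex <- run_explore(sim$fixes, sim$city$pois)
head(ex$indicators, 4)
#>   region_id      indicator  basis   value n_contributors
#> 1   sx0qcz1 steps_per_hour visits   70.67              6
#> 2   sx0qczu steps_per_hour visits 2296.14              6
#> 3   sx0qfpj steps_per_hour visits  270.61              6
#> 4   sx0qfrc steps_per_hour visits  119.61              6
```

Each row is one published geohash cell: `value` is the indicator in its
own units (steps/hour here), and `n_contributors` the number of visits,
unique visitors or residents behind it — always more than 5, because
1429 lower-support rows were suppressed in this run
(`ex$manifest$counts$rows_suppressed`).

```r
res <- run_explain(sim$fixes, sim$city$pois, sim$city$schools)
subset(res$associations, !is.na(p),
       c(behavior, basis, characteristic, n, r, ci_low, ci_high, p))
#>                 behavior    basis  characteristic   n       r ci_low ci_high        p
#>           steps_per_hour visitors  composite_food  80 -0.0135 -0.233  0.2068 9.05e-01
#>           steps_per_hour   visits  composite_food 118 -0.2138 -0.380 -0.0344 2.01e-02
#>  pct_visits_food_related   visits  composite_food 118  0.6117  0.485  0.7136 1.86e-13
#>     pct_visits_fast_food   visits count_fast_food 118  0.6570  0.540  0.7488 6.55e-16
#>  ...
```

The simulator coupled food-place visits to local food-POI density
(`beta_food = 2`), and the analysis recovers exactly that: strongly
positive, significant correlations for the place-visit percentages
(r ≈ 0.61–0.66 over 118 school-proximal cells), while step rates —
generated independently of the environment — stay near zero. Degenerate
pairs are flagged in `note` rather than silently dropped.

For an intervention analysis, give the simulator a per-municipality
after-period shift and compare periods:

```r
cfg2 <- sim_config(seed = 11, n_children = 40, n_days = 3, n_days_after = 3,
                   n_schools = 4, school_placement = "center",
                   activity_shift_after = c(m2 = 0.5))
sim2 <- simulate_study(cfg2)
pc <- pipeline_config(period_before = cfg2$period_before,
                      period_after = cfg2$period_after)
run_compare(sim2$fixes, sim2$city$municipalities, pc)$comparison
#>   municipality n_cells_before mean_before n_cells_after mean_after       t        df        p
#> 1           m1            140        3992           147       3912  0.3487  279.6    7.28e-01
#> 2           m2            146        3398           147       1685 12.7676  216.8    3.30e-28
#> 3           m3             77        3052            79       3037  0.0633  153.6    9.50e-01
#> 4           m4            144        2982           143       2899  0.5554  284.7    5.79e-01
#> 5        Total            507        3391           516       2863  5.1962 1019.6    2.46e-07
```

Only the municipality whose activity was halved (`m2`) is flagged.

A thin command-line wrapper with `simulate` / `explore` / `explain` /
`compare` subcommands lives at `inst/cli/obesogeo.R`; file formats are
trajectory/POI/school CSV, municipality GeoJSON, and CSV+JSON output
tables with a JSON run manifest.

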