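Package: obesogeo
Title: Geohash-Aggregated Obesogenic Behavior Indicators from Child GPS and Step Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts timestamped GPS and step-count trajectories of a child
    cohort into privacy-preserving geohash-aggregated behavioral indicators
    (step rates across visits, visitors and residents; percentages of visits
    that include contact with food- or sports-related places), characterizes
    the local environment from point-of-interest layers (per-cell counts,
    grid-based radius densities, Food and Sports composites), extracts
    behavior-environment Pearson associations in school-proximal geohashes
    stratified by city, and compares municipality-level behavior between two
    time periods with Welch's t test. Includes a synthetic-city and
    synthetic-cohort simulator with configurable environment-to-behavior
    couplings so that every pipeline stage can be validated against known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    geosphere,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
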