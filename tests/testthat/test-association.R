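test_that("pearson_test matches the brute-force formulas and stats::cor.test", {
  expect_equal(pearson_test(1:10, 1:10)$r, 1)
  expect_equal(pearson_test(c(1, 2, 3), c(3, 2, 1))$r, -1)
  set.seed(53)
  for (i in 1:1000) {
    n <- sample(4:40, 1)
    x <- rnorm(n); y <- rnorm(n) + 0.3 * x
    got <- pearson_test(x, y)
    want <- oracle_pearson(x, y)
    expect_equal(got$r, want$r, tolerance = 1e-12)
    expect_equal(got$p, want$p, tolerance = 1e-12)
    expect_equal(got$ci_low, want$ci_low, tolerance = 1e-12)
    expect_equal(got$ci_high, want$ci_high, tolerance = 1e-12)
  }
  # independent implementation cross-check
  set.seed(59)
  x <- rnorm(25); y <- rnorm(25)
  ct <- stats::cor.test(x, y)
  got <- pearson_test(x, y)
  expect_equal(got$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(got$p, ct$p.value, tolerance = 1e-12)
  expect_equal(c(got$ci_low, got$ci_high), as.numeric(ct$conf.int),
               tolerance = 1e-12)
})

test_that("pearson_test enforces its preconditions and CI ordering", {
  expect_error(pearson_test(1:2, 1:2), "insufficient")
  expect_error(pearson_test(rep(1, 5), 1:5), "zero variance")
  set.seed(61)
  x <- rnorm(30); y <- rnorm(30)
  got <- pearson_test(x, y)
  expect_true(got$ci_low <= got$r && got$r <= got$ci_high)
  expect_true(got$p >= 0 && got$p <= 1)
})

test_that("pearson correlation is affine-invariant with sign under slope", {
  set.seed(67)
  x <- rnorm(40); y <- rnorm(40) + 0.5 * x
  r0 <- pearson_test(x, y)$r
  expect_equal(pearson_test(3 * x + 7, y)$r, r0, tolerance = 1e-12)
  expect_equal(pearson_test(x, 0.1 * y - 2)$r, r0, tolerance = 1e-12)
  expect_equal(pearson_test(-2 * x, y)$r, -r0, tolerance = 1e-12)
})

test_that("school-proximal selection is strict at the radius and deduplicated", {
  # cells roughly 0, 500 and 1500 m east of the school
  sch_lat <- 40.6; sch_lon <- 22.95
  deg <- 1 / (111320 * cos(sch_lat * pi / 180))
  cells <- geohash_encode(rep(sch_lat, 3),
                          sch_lon + c(0, 500, 1500) * deg, 7L)
  schools <- data.frame(id = "s1", lat = sch_lat, lon = sch_lon)
  sel <- select_school_geohashes(cells, schools, 1000)
  expect_setequal(sel, cells[1:2])
  # strictness: radius equal to the exact center distance excludes the cell
  ctr <- geohash_decode(cells[2])
  d <- haversine_m(ctr$lat, ctr$lon, sch_lat, sch_lon)
  expect_false(cells[2] %in% select_school_geohashes(cells, schools, d))
  expect_true(cells[2] %in% select_school_geohashes(cells, schools, d + 1e-6))
  # a cell near two schools appears once
  schools2 <- rbind(schools, data.frame(id = "s2", lat = sch_lat,
                                        lon = sch_lon + 100 * deg))
  sel2 <- select_school_geohashes(cells, schools2, 1000)
  expect_equal(anyDuplicated(sel2), 0L)
  # selection is a subset and grows with the radius
  expect_true(all(sel %in% cells))
  for (r in c(200, 600, 1200, 2000)) {
    expect_true(all(select_school_geohashes(cells, schools, r) %in%
                      select_school_geohashes(cells, schools, r + 500)))
  }
  expect_error(select_school_geohashes(substr(cells, 1, 6), schools, 1000),
               "precision")
})

test_that("associate joins per city and flags degenerate pairs", {
  sch_lat <- 40.6; sch_lon <- 22.95
  deg <- 1 / (111320 * cos(sch_lat * pi / 180))
  cells <- geohash_encode(rep(sch_lat, 6),
                          sch_lon + seq(0, 800, 160) * deg, 7L)
  ind <- data.frame(region_id = cells, indicator = "steps_per_hour",
                    basis = "visits", value = c(1, 3, 2, 5, 4, 6),
                    n_contributors = 10L, stringsAsFactors = FALSE)
  env <- data.frame(cell = cells, characteristic = "composite_food",
                    value = c(2, 4, 3, 6, 5, 7), stringsAsFactors = FALSE)
  schools <- data.frame(id = "s1", lat = sch_lat, lon = sch_lon,
                        city = "alpha")
  pairing <- data.frame(indicator = "steps_per_hour", basis = "visits",
                        characteristic = "composite_food",
                        stringsAsFactors = FALSE)
  a <- associate(ind, env, schools, pairing)
  expect_equal(a$n, 6)
  expect_equal(a$r, 1)  # env constructed as value + 1
  expect_identical(a$city, "alpha")

  # constant environment -> flagged, not dropped
  env0 <- env; env0$value <- 5
  a0 <- associate(ind, env0, schools, pairing)
  expect_match(a0$note, "zero variance")
  expect_true(is.na(a0$r))

  # too few joined cells -> flagged
  a1 <- associate(ind[1:2, ], env, schools, pairing)
  expect_match(a1$note, "insufficient")
})

test_that("per-city stratification undoes a pooled confounding trend", {
  # two cities; within each city behavior decreases with the
  # characteristic, but city-level offsets make the pooled trend positive
  mk_city <- function(lat0, lon0, base) {
    deg <- 1 / (111320 * cos(lat0 * pi / 180))
    cells <- geohash_encode(rep(lat0, 5), lon0 + seq(0, 640, 160) * deg, 7L)
    list(cells = cells,
         ind = data.frame(region_id = cells, indicator = "steps_per_hour",
                          basis = "visits",
                          value = base - c(1, 2, 3, 4, 5) * 0.5,
                          n_contributors = 10L, stringsAsFactors = FALSE),
         env = data.frame(cell = cells, characteristic = "composite_food",
                          value = base / 10 + c(1, 2, 3, 4, 5),
                          stringsAsFactors = FALSE))
  }
  c1 <- mk_city(40.6, 22.95, 10)
  c2 <- mk_city(41.6, 23.95, 100)
  ind <- rbind(c1$ind, c2$ind); env <- rbind(c1$env, c2$env)
  schools <- data.frame(id = c("s1", "s2"), lat = c(40.6, 41.6),
                        lon = c(22.95, 23.95), city = c("alpha", "beta"))
  pairing <- data.frame(indicator = "steps_per_hour", basis = "visits",
                        characteristic = "composite_food",
                        stringsAsFactors = FALSE)
  a <- associate(ind, env, schools, pairing)
  expect_equal(nrow(a), 2)
  expect_true(all(a$r < 0))  # within-city truth is negative
  # pooled correlation across cities would have been positive
  pooled <- pearson_test(ind$value, env$value[match(ind$region_id,
                                                    env$cell)])
  expect_gt(pooled$r, 0)
})

test_that("optional Benjamini-Hochberg adjustment is off by default", {
  set.seed(71)
  sch_lat <- 40.6; sch_lon <- 22.95
  deg <- 1 / (111320 * cos(sch_lat * pi / 180))
  cells <- geohash_encode(rep(sch_lat, 8),
                          sch_lon + seq(0, 1120, 160) * deg, 7L)
  ind <- data.frame(region_id = rep(cells, 2),
                    indicator = rep(c("steps_per_hour",
                                      "pct_visits_fast_food"), each = 8),
                    basis = "visits", value = rnorm(16),
                    n_contributors = 10L, stringsAsFactors = FALSE)
  env <- rbind(
    data.frame(cell = cells, characteristic = "composite_food",
               value = rnorm(8), stringsAsFactors = FALSE),
    data.frame(cell = cells, characteristic = "count_fast_food",
               value = rnorm(8), stringsAsFactors = FALSE))
  schools <- data.frame(id = "s1", lat = sch_lat, lon = sch_lon)
  pairing <- data.frame(
    indicator = c("steps_per_hour", "pct_visits_fast_food"),
    basis = "visits",
    characteristic = c("composite_food", "count_fast_food"),
    stringsAsFactors = FALSE)
  raw <- associate(ind, env, schools, pairing)
  expect_null(raw$p_adjusted)
  adj <- associate(ind, env, schools, pairing, p_adjust = "BH")
  expect_equal(adj$p_adjusted, stats::p.adjust(adj$p, "BH"))
})
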