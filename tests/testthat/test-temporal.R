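test_that("welch_t_test matches the formula oracle and stats::t.test", {
  set.seed(73)
  for (i in 1:1000) {
    a <- rnorm(sample(3:30, 1), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(3:30, 1), mean = runif(1, -1, 1),
               sd = runif(1, 0.5, 3))
    got <- welch_t_test(a, b)
    want <- oracle_welch(a, b)
    expect_equal(got$t, want$t, tolerance = 1e-10)
    expect_equal(got$df, want$df, tolerance = 1e-10)
    expect_equal(got$p, want$p, tolerance = 1e-10)
  }
  a <- rnorm(12); b <- rnorm(20, 0.5)
  tt <- stats::t.test(a, b)
  got <- welch_t_test(a, b)
  expect_equal(got$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(got$df, unname(tt$parameter), tolerance = 1e-12)
  expect_equal(got$p, tt$p.value, tolerance = 1e-12)
})

test_that("welch_t_test degenerate and symmetry behavior", {
  a <- c(1, 2, 3, 4)
  r <- welch_t_test(a, a)
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  b <- c(4, 5, 6)
  fwd <- welch_t_test(c(1, 2, 3), b)
  rev <- welch_t_test(b, c(1, 2, 3))
  expect_equal(fwd$t, -rev$t)
  expect_equal(fwd$p, rev$p)
  expect_error(welch_t_test(1, c(1, 2)), "insufficient")
  expect_error(welch_t_test(c(1, 1), c(2, 2)), "zero variance")
})

test_that("cells map to the first containing municipality, borders uniquely", {
  sq <- function(x0, x1, y0, y1) {
    list(rings = list(cbind(c(x0, x1, x1, x0, x0), c(y0, y0, y1, y1, y0))))
  }
  west <- c(sq(22.90, 22.95, 40.58, 40.66), name = "west")
  east <- c(sq(22.95, 23.00, 40.58, 40.66), name = "east")
  munis <- list(west, east)
  cells <- geohash_encode(c(40.6, 40.6, 40.0),
                          c(22.92, 22.97, 22.92), 7L)
  got <- cells_in_municipality(cells, munis)
  expect_identical(got, c("west", "east", NA_character_))
  # a center exactly on the shared border goes to the first municipality
  ctr_lon <- 22.95
  border_cell <- geohash_encode(40.6, ctr_lon, 7L)
  box <- geohash_decode(border_cell)
  shifted <- list(
    c(sq(22.90, box$lon, 40.58, 40.66), name = "A"),
    c(sq(box$lon, 23.00, 40.58, 40.66), name = "B"))
  expect_identical(cells_in_municipality(border_cell, shifted), "A")
  expect_identical(cells_in_municipality(border_cell, rev(shifted)), "B")
})

test_that("municipal series filter by period, municipality and support", {
  cellA <- geohash_encode(40.60, 22.92, 7L)
  cellB <- geohash_encode(40.60, 22.97, 7L)
  v <- rbind(
    make_visits(c("a", "b"), cellA, 60, c(100, 300),
                t_entry = as.POSIXct("2020-01-10 10:00:00", tz = "UTC")),
    make_visits("a", cellA, 60, 500,
                t_entry = as.POSIXct("2020-03-15 10:00:00", tz = "UTC")),
    make_visits("a", cellB, 60, 900,
                t_entry = as.POSIXct("2020-01-10 10:00:00", tz = "UTC")))
  muni_of <- stats::setNames(c("west", "east"), c(cellA, cellB))
  before <- period_spec("before", "2020-01-08", "2020-03-10")
  after <- period_spec("after", "2020-03-11", "2020-03-31")
  s_before <- municipal_series(v, "west", muni_of, before)
  expect_equal(unname(s_before), 200)  # mean of 100 and 300 steps/h
  s_after <- municipal_series(v, "west", muni_of, after)
  expect_equal(unname(s_after), 500)
  # support threshold: the before cell has 2 users, the after one only 1
  expect_equal(length(municipal_series(v, "west", muni_of, after,
                                       min_support = 2L)), 0)
  expect_equal(unname(municipal_series(v, "east", muni_of, before)), 900)
})

test_that("periods validate and overlapping periods are a config error", {
  expect_error(period_spec("x", "2020-05-01", "2020-04-01"), "start after end")
  expect_error(period_spec("x", "not-a-date", "2020-04-01"))
  b <- period_spec("before", "2020-01-08", "2020-03-10")
  a <- period_spec("after", "2020-03-01", "2020-03-31")
  cfg <- pipeline_config(period_before = b, period_after = a)
  expect_error(run_compare(make_fixes(), list(), cfg), "overlap")
  expect_error(run_compare(make_fixes(), list(),
                           pipeline_config(period_before = b)),
               "config error")
})

test_that("compare_periods reports per-municipality rows plus a Total row", {
  set.seed(79)
  sq <- function(x0, x1) {
    list(rings = list(cbind(c(x0, x1, x1, x0, x0),
                            c(40.58, 40.58, 40.66, 40.66, 40.58))))
  }
  munis <- list(c(sq(22.90, 22.95), name = "west"),
                c(sq(22.95, 23.00), name = "east"))
  before <- period_spec("before", "2020-01-08", "2020-03-10")
  after <- period_spec("after", "2020-03-11", "2020-03-31")

  mk <- function(lon0, t0, rate, n_cells = 8, visits_per_cell = 3) {
    deg <- 1 / (111320 * cos(40.6 * pi / 180))
    cells <- geohash_encode(rep(40.6, n_cells),
                            lon0 + (0:(n_cells - 1)) * 160 * deg, 7L)
    do.call(rbind, lapply(seq_along(cells), function(i) {
      make_visits(paste0("u", 1:visits_per_cell), cells[i], 60,
                  rpois(visits_per_cell, rate), t_entry = t0)
    }))
  }
  t_b <- as.POSIXct("2020-01-10 10:00:00", tz = "UTC")
  t_a <- as.POSIXct("2020-03-15 10:00:00", tz = "UTC")
  v <- rbind(mk(22.91, t_b, 300), mk(22.91, t_a, 300),   # west stable
             mk(22.96, t_b, 400), mk(22.96, t_a, 100))   # east halved twice
  cmp <- compare_periods(v, munis, before, after)
  expect_identical(cmp$municipality, c("west", "east", "Total"))
  expect_equal(cmp$n_cells_before, c(8, 8, 16))
  expect_equal(cmp$n_cells_after, c(8, 8, 16))
  expect_gt(cmp$p[cmp$municipality == "west"], 0.001)
  expect_lt(cmp$p[cmp$municipality == "east"], 1e-4)
  expect_gt(cmp$mean_before[cmp$municipality == "east"],
            cmp$mean_after[cmp$municipality == "east"])
  # the Total mean lies between the municipality means
  expect_gte(cmp$mean_before[3], min(cmp$mean_before[1:2]))
  expect_lte(cmp$mean_before[3], max(cmp$mean_before[1:2]))

  # a municipality with no after-period data is flagged, not dropped
  v2 <- v[as.Date(v$t_entry) <= before$end |
            cells_in_municipality(v$cell, munis) == "west", ]
  cmp2 <- compare_periods(v2, munis, before, after)
  expect_match(cmp2$note[cmp2$municipality == "east"], "not computable")
})
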