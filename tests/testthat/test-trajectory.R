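test_that("trajectory CSV reading validates rows and names bad lines", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("child_id,timestamp,lat,lon,steps",
               "c1,2020-01-08T09:00:00Z,40.6,22.95,10",
               "c1,2020-01-08T09:01:00Z,40.6,22.95,12",
               "c2,2020-01-08T09:00:30Z,40.61,22.96,5"), path)
  fx <- read_fixes(path)
  expect_equal(nrow(fx), 3)
  expect_s3_class(fx$t, "POSIXct")
  expect_identical(fx$child_id, c("c1", "c1", "c2"))
  expect_true(all(diff(as.numeric(fx$t[1:2])) > 0))

  # empty file with header only
  writeLines("child_id,timestamp,lat,lon,steps", path)
  expect_equal(nrow(read_fixes(path)), 0)

  # out-of-range latitude: lenient skips with the line number, strict stops
  writeLines(c("child_id,timestamp,lat,lon,steps",
               "c1,2020-01-08T09:00:00Z,95,22.95,10",
               "c1,2020-01-08T09:01:00Z,40.6,22.95,1"), path)
  expect_warning(fx <- read_fixes(path), "line 2")
  expect_equal(nrow(fx), 1)
  expect_error(read_fixes(path, strict = TRUE), "line 2")

  # duplicate timestamp for one child is rejected
  writeLines(c("child_id,timestamp,lat,lon,steps",
               "c1,2020-01-08T09:00:00Z,40.6,22.95,10",
               "c1,2020-01-08T09:00:00Z,40.6,22.95,3"), path)
  expect_warning(fx <- read_fixes(path), "duplicate")
  expect_equal(nrow(fx), 1)
})

test_that("visit segmentation applies the duration filter and step attribution", {
  # single fix: zero duration, no visit
  expect_equal(nrow(segment_visits(make_fixes(times_s = 0))), 0)
  # 30 s in one cell is below the 1-minute rule
  expect_equal(nrow(segment_visits(make_fixes(times_s = c(0, 30)))), 0)
  # 2 minutes with steps 10 + 20 after entry: one visit, steps 30
  fx <- make_fixes(times_s = c(0, 60, 120), steps = c(5, 10, 20))
  v <- segment_visits(fx)
  expect_equal(nrow(v), 1)
  expect_equal(v$duration_min, 2)
  expect_equal(v$steps, 30)  # the entry fix's increment is excluded
  expect_identical(v$cell, geohash_encode(fx$lat[1], fx$lon[1], 7L))
})

test_that("a long gap splits a stay into separate visits", {
  fx <- make_fixes(times_s = c(0, 60, 120, 1000, 1060, 1120), steps = 1)
  v <- segment_visits(fx, max_gap_min = 5)
  expect_equal(nrow(v), 2)
  expect_true(all(v$duration_min == 2))
  # with a tolerant gap the same fixes form one visit
  v1 <- segment_visits(fx, max_gap_min = 20)
  expect_equal(nrow(v1), 1)
})

test_that("visits never overlap and durations are bounded by recorded time", {
  set.seed(21)
  # random walk near a cell boundary to force frequent cell changes
  n <- 400
  fx <- data.frame(
    child_id = sample(c("a", "b"), n, replace = TRUE),
    t = as.POSIXct("2020-01-08", tz = "UTC") +
      sort(sample.int(50000, n)),
    lat = 40.6 + cumsum(rnorm(n, 0, 2e-4)),
    lon = 22.95 + cumsum(rnorm(n, 0, 2e-4)),
    steps = rpois(n, 5), stringsAsFactors = FALSE
  )
  fx <- validate_fixes(fx)
  v <- segment_visits(fx, min_duration_min = 0.5)
  for (ch in unique(v$child_id)) {
    vi <- v[v$child_id == ch, ]
    vi <- vi[order(vi$t_entry), ]
    if (nrow(vi) > 1) {
      expect_true(all(as.numeric(vi$t_entry[-1]) >=
                        as.numeric(vi$t_exit[-nrow(vi)])))
    }
    span <- diff(range(as.numeric(fx$t[fx$child_id == ch]))) / 60
    expect_lte(sum(vi$duration_min), span)
  }
  # raising the duration threshold can only remove visits
  n_at <- vapply(c(0, 0.5, 1, 2, 5, 10), function(m) {
    nrow(segment_visits(fx, min_duration_min = m))
  }, numeric(1))
  expect_true(all(diff(n_at) <= 0))
})

test_that("precision-7 visits nest inside precision-6 visit spans", {
  set.seed(33)
  n <- 300
  fx <- validate_fixes(data.frame(
    child_id = "a",
    t = as.POSIXct("2020-01-08", tz = "UTC") + seq_len(n) * 30,
    lat = 40.6 + cumsum(rnorm(n, 0, 1e-4)),
    lon = 22.95 + cumsum(rnorm(n, 0, 1e-4)),
    steps = 1, stringsAsFactors = FALSE
  ))
  v7 <- segment_visits(fx, precision = 7L, min_duration_min = 1)
  v6 <- segment_visits(fx, precision = 6L, min_duration_min = 1)
  for (i in seq_len(nrow(v7))) {
    host <- v6[v6$cell == substr(v7$cell[i], 1, 6) &
                 v6$t_entry <= v7$t_entry[i] &
                 v6$t_exit >= v7$t_exit[i], ]
    expect_gte(nrow(host), 1)
  }
})

test_that("POI contacts require proximity and sustained dwell", {
  # 5 minutes at 10 m from a fast-food POI, radius 50, dwell 2 -> contact
  fx <- make_fixes(times_s = seq(0, 300, 60))
  v <- segment_visits(fx)
  pois <- make_pois(east_m = 10)
  v1 <- attach_poi_contacts(v, fx, pois, contact_radius_m = 50,
                            min_dwell_min = 2)
  expect_equal(v1$contacts_fast_food, 1L)

  # far POI: no contact; absent categories get zero-filled columns
  pois2 <- make_pois(east_m = 500, category = c("fast_food", "public_park"))
  v2 <- attach_poi_contacts(v, fx, pois2, 50, 1)
  expect_equal(v2$contacts_fast_food, 0L)
  expect_equal(v2$contacts_public_park, 0L)

  # two POIs of one category both within radius -> category count 2
  pois3 <- make_pois(east_m = c(10, -10))
  v3 <- attach_poi_contacts(v, fx, pois3, 50, 2)
  expect_equal(v3$contacts_fast_food, 2L)

  # brief pass within radius (< dwell) does not count
  fx4 <- make_fixes(times_s = c(0, 20, 300), lon = 22.95)
  fx4$lon <- c(22.95, 22.95, 22.9505)  # leaves the radius after 20 s
  v4 <- segment_visits(fx4, min_duration_min = 1, max_gap_min = 10)
  v4 <- attach_poi_contacts(v4, fx4, make_pois(east_m = 0), 50, 2)
  expect_true(all(v4$contacts_fast_food == 0L))
})

test_that("day summaries cap gap credit and split by calendar day", {
  # 45 minutes of 1-min fixes -> 45 recorded minutes
  fx <- make_fixes(times_s = seq(0, 45 * 60, 60), steps = 2)
  d <- summarize_days(fx)
  expect_equal(nrow(d), 1)
  expect_equal(d$recorded_min, 45)
  expect_equal(d$steps, sum(fx$steps))

  # two days with 90 and 30 recorded minutes
  fx2 <- rbind(make_fixes(times_s = seq(0, 90 * 60, 60)),
               make_fixes(times_s = seq(0, 30 * 60, 60),
                          t0 = as.POSIXct("2020-01-09 09:00:00",
                                          tz = "UTC")))
  d2 <- summarize_days(fx2)
  expect_equal(d2$recorded_min, c(90, 30))

  # a 2-hour outage contributes at most max_gap_min
  fx3 <- make_fixes(times_s = c(0, 60, 7260, 7320))
  expect_equal(summarize_days(fx3, max_gap_min = 5)$recorded_min, 2 + 5)

  expect_equal(nrow(summarize_days(make_fixes(times_s = numeric(0)))), 0)
})

test_that("residence is the nighttime-modal cell with lexicographic ties", {
  t_night <- as.POSIXct("2020-01-08 01:00:00", tz = "UTC")
  # 5 hours in cell A, 1 hour in cell B at night -> A
  fxA <- make_fixes(times_s = seq(0, 5 * 3600, 600), lat = 40.60,
                    t0 = t_night)
  fxB <- make_fixes(times_s = seq(0, 3600, 600), lat = 40.55,
                    t0 = t_night + 5 * 3600 + 600)
  fx <- validate_fixes(rbind(fxA, fxB))
  res <- assign_residence(fx, 7L)
  expect_identical(res$cell, geohash_encode(40.60, 22.95, 7L))

  # equal nighttime in two cells -> lexicographically smaller code
  fx2 <- validate_fixes(rbind(
    make_fixes(times_s = seq(0, 3600, 600), lat = 40.60, t0 = t_night),
    make_fixes(times_s = seq(0, 3600, 600), lat = 40.55,
               t0 = t_night + 2 * 3600)))
  cells <- geohash_encode(c(40.60, 40.55), c(22.95, 22.95), 7L)
  expect_identical(assign_residence(fx2, 7L)$cell, min(cells))

  # daytime-only child: residence undefined
  fx3 <- make_fixes(times_s = seq(0, 3600, 600))
  expect_true(is.na(assign_residence(fx3, 7L)$cell))
})
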