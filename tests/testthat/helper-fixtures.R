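# Programmatic fixture builders shared by the unit tests.

# Fixes for one child at a fixed location: `times_s` are offsets in
# seconds from `t0`; `steps` recycled to match.
make_fixes <- function(child = "c1", times_s = c(0, 60, 120),
                       lat = 40.6, lon = 22.95, steps = 0,
                       t0 = as.POSIXct("2020-01-08 09:00:00", tz = "UTC")) {
  n <- length(times_s)
  data.frame(child_id = rep_len(child, n), t = t0 + times_s,
             lat = rep_len(lat, n), lon = rep_len(lon, n),
             steps = rep_len(steps, n), stringsAsFactors = FALSE)
}

# A minimal visit table (already segmented), one row per visit.
make_visits <- function(child, cell, duration_min, steps,
                        t_entry = as.POSIXct("2020-01-08 09:00:00",
                                             tz = "UTC")) {
  n <- max(length(child), length(cell), length(duration_min),
           length(steps))
  child <- rep_len(child, n); cell <- rep_len(cell, n)
  duration_min <- rep_len(duration_min, n); steps <- rep_len(steps, n)
  t_entry <- rep_len(t_entry, n)
  data.frame(child_id = child, cell = cell, t_entry = t_entry,
             t_exit = t_entry + duration_min * 60,
             duration_min = duration_min, steps = steps,
             n_fixes = 2L, row_start = NA_integer_, row_end = NA_integer_,
             stringsAsFactors = FALSE)
}

# Small POI layer around a center point; offsets in meters east/north.
make_pois <- function(center_lat = 40.6, center_lon = 22.95,
                      east_m = 0, north_m = 0, category = "fast_food") {
  n <- max(length(east_m), length(north_m), length(category))
  east_m <- rep_len(east_m, n); north_m <- rep_len(north_m, n)
  category <- rep_len(category, n)
  deg_lat <- 1 / 111320
  deg_lon <- deg_lat / cos(center_lat * pi / 180)
  data.frame(id = paste0("p", seq_len(n)), category = category,
             lat = center_lat + north_m * deg_lat,
             lon = center_lon + east_m * deg_lon,
             stringsAsFactors = FALSE)
}

# Tiny simulation config for fast pipeline tests; `...` overrides any
# of the small defaults.
tiny_sim_config <- function(seed = 101, ...) {
  args <- list(seed = seed, n_children = 15L, n_days = 2L, n_schools = 2L,
               bbox = c(lat_min = 40.60, lat_max = 40.63,
                        lon_min = 22.92, lon_max = 22.96))
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}
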