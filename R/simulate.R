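# Synthetic city and child cohort with known environment-behavior
# couplings.
#
# The generator emulates the kind of cohort the pipeline is built for:
# school children carrying a phone, a home and a school anchor per
# child, a daily home -> school -> after-school wander -> home routine,
# POI stop probabilities coupled to the local POI density through a
# logistic link, context-dependent step rates, GPS jitter and fix
# dropout. Movement between anchors is straight-line walking - adequate
# for visit segmentation and step accounting, which never look at road
# geometry.

.m_per_deg_lat <- 111320

#' Build a simulation configuration
#'
#' Defaults describe the reference study conditions used throughout the
#' package's validation: a roughly 7 x 7 km city, 200 children observed
#' for 14 days at one fix per minute with 10% dropout, six schools,
#' POI intensities that peak downtown for food categories, and a
#' logistic density-to-stop-probability coupling of 2 per standard
#' deviation of local density.
#'
#' @param seed Integer RNG seed; a fixed seed makes every generated
#'   file byte-identical.
#' @param n_children,n_days,n_days_after Cohort size and number of
#'   simulated days in the before and after periods.
#' @param bbox Named numeric: `lat_min`, `lat_max`, `lon_min`,
#'   `lon_max`.
#' @param n_schools Number of schools.
#' @param school_placement `"uniform"` (anywhere in the box) or
#'   `"center"` (one school near the center of each municipality,
#'   useful for clean per-municipality intervention experiments).
#' @param muni_nx,muni_ny Municipality grid: the city box is
#'   partitioned into `muni_nx * muni_ny` rectangles named `m1`,
#'   `m2`, ...
#' @param poi_intensities Named numeric, points per square kilometer
#'   per category.
#' @param downtown_peak Named numeric per category: amplitude of the
#'   Gaussian downtown intensity peak (0 = spatially homogeneous).
#' @param beta_food,beta_sports Logistic coupling of the per-cell POI
#'   density (standardized across the city's cells) to the stop
#'   probability; 0 decouples behavior from the environment.
#' @param alpha_food,alpha_sports Logistic intercepts (log-odds of a
#'   stop at average density).
#' @param base_step_rate Baseline steps/hour; contexts scale it (home
#'   0.25x, school 0.6x, walking 10x, POI/wander dwell 3x).
#' @param rate_dispersion Lognormal sigma of the per-child activity
#'   multiplier.
#' @param activity_shift_after Named numeric, multiplicative after-
#'   period step-rate factor per municipality (default 1 everywhere);
#'   applied by the child's home municipality.
#' @param fix_interval_s Sampling period of daytime fixes, seconds.
#' @param dropout Probability that a scheduled fix is missing.
#' @param jitter_m GPS noise standard deviation, meters.
#' @param n_wander,wander_radius_m After-school wander: number of
#'   stops and their radius around the school, meters.
#' @param walk_speed_ms Walking speed, m/s.
#' @param precision Working geohash precision.
#' @param period_before,period_after [period_spec()] objects giving
#'   the calendar windows the simulated days fall in.
#' @param city_name City label carried by the schools.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_children = 200L,
                       n_days = 14L,
                       n_days_after = 0L,
                       bbox = c(lat_min = 40.58, lat_max = 40.64,
                                lon_min = 22.90, lon_max = 22.98),
                       n_schools = 6L,
                       school_placement = c("uniform", "center"),
                       muni_nx = 2L, muni_ny = 2L,
                       poi_intensities = c(fast_food = 6, restaurant = 10,
                                           supermarket = 4,
                                           sports_facility = 3,
                                           indoor_recreation = 2,
                                           public_park = 1.5),
                       downtown_peak = c(fast_food = 2, restaurant = 2,
                                         supermarket = 1,
                                         sports_facility = 0.5,
                                         indoor_recreation = 0.5,
                                         public_park = 0.5),
                       beta_food = 2, beta_sports = 2,
                       alpha_food = stats::qlogis(0.2),
                       alpha_sports = stats::qlogis(0.1),
                       base_step_rate = 400, rate_dispersion = 0.3,
                       activity_shift_after = NULL,
                       fix_interval_s = 60, dropout = 0.1,
                       jitter_m = 3,
                       n_wander = 3L, wander_radius_m = 600,
                       walk_speed_ms = 1.3,
                       precision = 7L,
                       period_before = period_spec("before", "2020-01-08",
                                                   "2020-03-10"),
                       period_after = period_spec("after", "2020-03-11",
                                                  "2020-03-31"),
                       city_name = "simcity") {
  school_placement <- match.arg(school_placement)
  if (bbox["lat_max"] <= bbox["lat_min"] ||
      bbox["lon_max"] <= bbox["lon_min"]) {
    stop("zero-area city bounding box", call. = FALSE)
  }
  if (any(poi_intensities < 0) || base_step_rate < 0 || dropout < 0 ||
      dropout > 1 || fix_interval_s <= 0 || walk_speed_ms <= 0) {
    stop("rates must be non-negative, dropout in [0,1]", call. = FALSE)
  }
  cfg <- list(seed = as.integer(seed), n_children = as.integer(n_children),
              n_days = as.integer(n_days),
              n_days_after = as.integer(n_days_after), bbox = bbox,
              n_schools = as.integer(n_schools),
              school_placement = school_placement,
              muni_nx = as.integer(muni_nx), muni_ny = as.integer(muni_ny),
              poi_intensities = poi_intensities,
              downtown_peak = downtown_peak,
              beta_food = beta_food, beta_sports = beta_sports,
              alpha_food = alpha_food, alpha_sports = alpha_sports,
              base_step_rate = base_step_rate,
              rate_dispersion = rate_dispersion,
              activity_shift_after = activity_shift_after,
              fix_interval_s = fix_interval_s, dropout = dropout,
              jitter_m = jitter_m, n_wander = as.integer(n_wander),
              wander_radius_m = wander_radius_m,
              walk_speed_ms = walk_speed_ms,
              precision = as.integer(precision),
              period_before = period_before, period_after = period_after,
              city_name = city_name)
  class(cfg) <- "sim_config"
  cfg
}

.muni_rectangles <- function(cfg) {
  b <- cfg$bbox
  lat_br <- seq(b["lat_min"], b["lat_max"], length.out = cfg$muni_ny + 1L)
  lon_br <- seq(b["lon_min"], b["lon_max"], length.out = cfg$muni_nx + 1L)
  out <- list()
  k <- 0L
  for (iy in seq_len(cfg$muni_ny)) {
    for (ix in seq_len(cfg$muni_nx)) {
      k <- k + 1L
      ring <- cbind(lon = c(lon_br[ix], lon_br[ix + 1L], lon_br[ix + 1L],
                            lon_br[ix], lon_br[ix]),
                    lat = c(lat_br[iy], lat_br[iy], lat_br[iy + 1L],
                            lat_br[iy + 1L], lat_br[iy]))
      out[[k]] <- list(name = paste0("m", k), rings = list(ring))
    }
  }
  out
}

.muni_of_point <- function(cfg, lat, lon) {
  b <- cfg$bbox
  ix <- pmin(pmax(ceiling((lon - b["lon_min"]) /
                            (b["lon_max"] - b["lon_min"]) * cfg$muni_nx),
                  1L), cfg$muni_nx)
  iy <- pmin(pmax(ceiling((lat - b["lat_min"]) /
                            (b["lat_max"] - b["lat_min"]) * cfg$muni_ny),
                  1L), cfg$muni_ny)
  paste0("m", (iy - 1L) * cfg$muni_nx + ix)
}

.enumerate_cells <- function(bbox, precision) {
  nbits <- 5L * precision
  nlon <- ceiling(nbits / 2)
  nlat <- floor(nbits / 2)
  dlat <- 180 / 2^nlat
  dlon <- 360 / 2^nlon
  lat0 <- (floor((bbox["lat_min"] + 90) / dlat) + 0.5) * dlat - 90
  lon0 <- (floor((bbox["lon_min"] + 180) / dlon) + 0.5) * dlon - 180
  lats <- seq(lat0, bbox["lat_max"] + dlat / 2, by = dlat)
  lons <- seq(lon0, bbox["lon_max"] + dlon / 2, by = dlon)
  g <- expand.grid(lat = lats, lon = lons)
  unique(geohash_encode(g$lat, g$lon, precision))
}

#' Generate a synthetic city
#'
#' POIs are drawn per category from an inhomogeneous Poisson point
#' process (a Gaussian intensity peak toward the city center emulates a
#' downtown, via thinning of a homogeneous process at the maximum
#' intensity); municipalities are a deterministic rectangular partition
#' of the box; schools are placed uniformly (or one per municipality
#' near its center). Per-cell true POI counts and their standardized
#' densities - the quantities the behavioral coupling acts on - are
#' tabulated in `$cells`.
#'
#' @param cfg A [sim_config()].
#' @return A list: `bbox`, `municipalities`, `schools` (data.frame
#'   `id`, `lat`, `lon`, `city`), `pois` (data.frame `id`, `category`,
#'   `lat`, `lon`), `cells` (per-cell truth: counts per category,
#'   `food`, `sports`, `z_food`, `z_sports`), `precision`.
#' @export
generate_city <- function(cfg) {
  set.seed(cfg$seed)
  b <- cfg$bbox
  midlat <- (b["lat_min"] + b["lat_max"]) / 2
  km_lat <- (b["lat_max"] - b["lat_min"]) * .m_per_deg_lat / 1000
  km_lon <- (b["lon_max"] - b["lon_min"]) * .m_per_deg_lat *
    cos(midlat * pi / 180) / 1000
  area_km2 <- km_lat * km_lon
  ctr_lat <- midlat
  ctr_lon <- (b["lon_min"] + b["lon_max"]) / 2
  sigma_m <- 0.2 * min(km_lat, km_lon) * 1000

  pois <- list()
  for (cat in names(cfg$poi_intensities)) {
    lambda <- cfg$poi_intensities[[cat]]
    if (lambda <= 0) next
    peak <- if (cat %in% names(cfg$downtown_peak)) {
      cfg$downtown_peak[[cat]]
    } else 0
    lambda_max <- lambda * (1 + peak)
    n <- stats::rpois(1L, lambda_max * area_km2)
    if (n == 0L) next
    lat <- stats::runif(n, b["lat_min"], b["lat_max"])
    lon <- stats::runif(n, b["lon_min"], b["lon_max"])
    d <- haversine_m(lat, lon, ctr_lat, ctr_lon)
    accept <- stats::runif(n) <
      (1 + peak * exp(-d^2 / (2 * sigma_m^2))) / (1 + peak)
    if (!any(accept)) next
    pois[[cat]] <- data.frame(category = cat, lat = lat[accept],
                              lon = lon[accept], stringsAsFactors = FALSE)
  }
  pois <- if (length(pois)) do.call(rbind, pois) else {
    data.frame(category = character(0), lat = numeric(0),
               lon = numeric(0), stringsAsFactors = FALSE)
  }
  pois <- data.frame(id = paste0("poi", seq_len(nrow(pois))), pois,
                     stringsAsFactors = FALSE)
  rownames(pois) <- NULL

  if (cfg$school_placement == "center") {
    munis <- .muni_rectangles(cfg)
    ctrs <- t(vapply(munis, function(m) {
      colMeans(m$rings[[1L]][-nrow(m$rings[[1L]]), ])
    }, numeric(2)))
    idx <- rep_len(seq_len(nrow(ctrs)), cfg$n_schools)
    off <- 0.1 * c(b["lat_max"] - b["lat_min"], b["lon_max"] - b["lon_min"])
    s_lat <- ctrs[idx, 2L] + stats::runif(cfg$n_schools, -off[1L], off[1L]) / 4
    s_lon <- ctrs[idx, 1L] + stats::runif(cfg$n_schools, -off[2L], off[2L]) / 4
  } else {
    pad_lat <- 0.08 * (b["lat_max"] - b["lat_min"])
    pad_lon <- 0.08 * (b["lon_max"] - b["lon_min"])
    s_lat <- stats::runif(cfg$n_schools, b["lat_min"] + pad_lat,
                          b["lat_max"] - pad_lat)
    s_lon <- stats::runif(cfg$n_schools, b["lon_min"] + pad_lon,
                          b["lon_max"] - pad_lon)
  }
  schools <- data.frame(id = paste0("school", seq_len(cfg$n_schools)),
                        lat = s_lat, lon = s_lon, city = cfg$city_name,
                        stringsAsFactors = FALSE)

  cells <- .enumerate_cells(b, cfg$precision)
  cell_tab <- data.frame(cell = cells, stringsAsFactors = FALSE)
  cmap <- default_category_map()
  for (cat in names(cfg$poi_intensities)) {
    cnt <- integer(length(cells))
    p <- pois[pois$category == cat, , drop = FALSE]
    if (nrow(p)) {
      tab <- table(geohash_encode(p$lat, p$lon, cfg$precision))
      hit <- match(cells, names(tab))
      cnt <- ifelse(is.na(hit), 0L, as.integer(tab[hit]))
    }
    cell_tab[[cat]] <- cnt
  }
  food_cats <- intersect(cmap$category[cmap$group == "food"],
                         names(cell_tab))
  sport_cats <- intersect(cmap$category[cmap$group == "sports"],
                          names(cell_tab))
  cell_tab$food <- rowSums(as.matrix(cell_tab[, food_cats, drop = FALSE]))
  cell_tab$sports <- rowSums(as.matrix(cell_tab[, sport_cats, drop = FALSE]))
  zs <- function(x) (x - mean(x)) / max(stats::sd(x), 1e-9)
  cell_tab$z_food <- zs(cell_tab$food)
  cell_tab$z_sports <- zs(cell_tab$sports)

  list(bbox = b, municipalities = .muni_rectangles(cfg),
       schools = schools, pois = pois, cells = cell_tab,
       precision = cfg$precision)
}

#' Generate the cohort of children (homes, schools, activity levels)
#'
#' Deterministic given the configuration seed, so the true home cells
#' and municipality assignments can be re-derived independently of the
#' trajectories (see [ground_truth()]).
#'
#' @param cfg A [sim_config()].
#' @param city Output of [generate_city()].
#' @return Data.frame: `child_id`, `home_lat`, `home_lon`,
#'   `home_cell`, `municipality`, `school_id`, `rate_mult`.
#' @export
generate_children <- function(cfg, city) {
  set.seed(cfg$seed + 1L)
  b <- cfg$bbox
  lat <- stats::runif(cfg$n_children, b["lat_min"], b["lat_max"])
  lon <- stats::runif(cfg$n_children, b["lon_min"], b["lon_max"])
  d <- outer(seq_len(cfg$n_children), seq_len(nrow(city$schools)),
             function(i, j) haversine_m(lat[i], lon[i],
                                        city$schools$lat[j],
                                        city$schools$lon[j]))
  nearest <- apply(d, 1L, which.min)
  data.frame(
    child_id = sprintf("c%03d", seq_len(cfg$n_children)),
    home_lat = lat, home_lon = lon,
    home_cell = geohash_encode(lat, lon, cfg$precision),
    municipality = .muni_of_point(cfg, lat, lon),
    school_id = city$schools$id[nearest],
    rate_mult = stats::rlnorm(cfg$n_children, 0, cfg$rate_dispersion),
    stringsAsFactors = FALSE
  )
}

# context step-rate multipliers of the baseline steps/hour
.ctx_mult <- c(home = 0.25, school = 0.6, walk = 10, dwell = 3)

# fixes of one stationary episode: times at the fix interval
.seg_stationary <- function(t0, t1, lat, lon, interval, ctx) {
  if (t1 < t0) return(NULL)
  ts <- seq(t0, t1, by = interval)
  if (length(ts) == 0L) return(NULL)
  cbind(t = ts, lat = lat, lon = lon, ctx = ctx)
}

.seg_walk <- function(t0, lat1, lon1, lat2, lon2, speed, interval) {
  d <- haversine_m(lat1, lon1, lat2, lon2)
  dur <- d / speed
  if (dur < interval) {
    return(list(fix = NULL, t_end = t0 + dur))
  }
  ts <- seq(t0 + interval, t0 + dur, by = interval)
  f <- (ts - t0) / dur
  list(fix = cbind(t = ts, lat = lat1 + f * (lat2 - lat1),
                   lon = lon1 + f * (lon2 - lon1),
                   ctx = .ctx_seg["walk"]),
       t_end = t0 + dur)
}

.ctx_seg <- c(home = 1, school = 2, walk = 3, dwell = 4)

#' Simulate the cohort's trajectories
#'
#' Each simulated day follows home -> school -> after-school wander ->
#' home. Wander stops are sampled uniformly within
#' `wander_radius_m` of the school; at each stop the child makes a food
#' (or, failing that, sports) POI stop with probability
#' `plogis(alpha + beta * z)` where `z` is the city-standardized POI
#' density of the stop's geohash cell, and a POI stop relocates the
#' dwell to a matching POI of that cell - this is the ground-truth
#' coupling the association analysis is meant to recover. Step counts
#' are Poisson with context-dependent rates; after-period days multiply
#' the rate by the child's home-municipality `activity_shift_after`
#' factor. Fixes get GPS jitter and are thinned by `dropout`.
#'
#' @param cfg A [sim_config()].
#' @param city Output of [generate_city()].
#' @param children Optional pre-generated [generate_children()] table.
#' @return A fix data.frame (`child_id`, `t`, `lat`, `lon`, `steps`)
#'   sorted by (child, time), ready for [segment_visits()].
#' @export
generate_cohort <- function(cfg, city, children = generate_children(cfg, city)) {
  set.seed(cfg$seed + 2L)
  interval <- cfg$fix_interval_s
  midlat <- (cfg$bbox["lat_min"] + cfg$bbox["lat_max"]) / 2
  deg_lat <- 1 / .m_per_deg_lat
  deg_lon <- deg_lat / cos(midlat * pi / 180)

  # per-cell POI lookup for stop relocation
  poi_cell <- if (nrow(city$pois)) {
    geohash_encode(city$pois$lat, city$pois$lon, cfg$precision)
  } else character(0)
  cmap <- default_category_map()
  is_food <- city$pois$category %in% cmap$category[cmap$group == "food"]
  is_sport <- city$pois$category %in% cmap$category[cmap$group == "sports"]
  food_by_cell <- split(which(is_food), poi_cell[is_food])
  sport_by_cell <- split(which(is_sport), poi_cell[is_sport])
  z_food <- stats::setNames(city$cells$z_food, city$cells$cell)
  z_sports <- stats::setNames(city$cells$z_sports, city$cells$cell)
  z0_food <- min(city$cells$z_food)   # density-0 cells sit at the minimum
  z0_sport <- min(city$cells$z_sports)

  shift_of <- function(muni) {
    s <- cfg$activity_shift_after
    if (is.null(s) || !muni %in% names(s)) 1 else s[[muni]]
  }

  dates <- c(
    if (cfg$n_days > 0L) cfg$period_before$start + seq_len(cfg$n_days) - 1L,
    if (cfg$n_days_after > 0L)
      cfg$period_after$start + seq_len(cfg$n_days_after) - 1L
  )
  is_after <- c(rep(FALSE, cfg$n_days), rep(TRUE, cfg$n_days_after))

  sch <- city$schools
  out <- vector("list", nrow(children) * length(dates))
  k <- 0L
  for (i in seq_len(nrow(children))) {
    ch <- children[i, ]
    s <- sch[sch$id == ch$school_id, ]
    shift_after <- shift_of(ch$municipality)
    for (di in seq_along(dates)) {
      day0 <- as.numeric(as.POSIXct(paste(dates[di], "00:00:00"),
                                    tz = "UTC"))
      segs <- list()
      # night + morning at home
      segs[[1L]] <- .seg_stationary(1800, 21600, ch$home_lat, ch$home_lon,
                                    1800, .ctx_seg["home"])
      segs[[2L]] <- .seg_stationary(27000, 28800 - interval, ch$home_lat,
                                    ch$home_lon, interval,
                                    .ctx_seg["home"])
      w <- .seg_walk(28800, ch$home_lat, ch$home_lon, s$lat, s$lon,
                     cfg$walk_speed_ms, interval)
      segs[[3L]] <- w$fix
      t_sch <- max(w$t_end, 28800)
      segs[[4L]] <- .seg_stationary(t_sch + interval, 48600, s$lat, s$lon,
                                    interval, .ctx_seg["school"])
      # after-school wander
      cur_lat <- s$lat; cur_lon <- s$lon
      t_cur <- 48600
      if (cfg$n_wander > 0L) {
        rr <- cfg$wander_radius_m * sqrt(stats::runif(cfg$n_wander))
        th <- stats::runif(cfg$n_wander, 0, 2 * pi)
        for (wi in seq_len(cfg$n_wander)) {
          stop_lat <- s$lat + rr[wi] * sin(th[wi]) * deg_lat
          stop_lon <- s$lon + rr[wi] * cos(th[wi]) * deg_lon
          cell <- geohash_encode(stop_lat, stop_lon, cfg$precision)
          zf <- if (cell %in% names(z_food)) z_food[[cell]] else z0_food
          zsp <- if (cell %in% names(z_sports)) z_sports[[cell]] else z0_sport
          u <- stats::runif(2L)
          dwell_min <- stats::runif(1L, 3, 6)
          if (u[1L] < stats::plogis(cfg$alpha_food + cfg$beta_food * zf) &&
              !is.null(food_by_cell[[cell]])) {
            pk <- food_by_cell[[cell]]
            pk <- pk[sample.int(length(pk), 1L)]
            stop_lat <- city$pois$lat[pk] + stats::rnorm(1L, 0, 5 * deg_lat)
            stop_lon <- city$pois$lon[pk] + stats::rnorm(1L, 0, 5 * deg_lon)
            dwell_min <- stats::runif(1L, 4, 8)
          } else if (u[2L] < stats::plogis(cfg$alpha_sports +
                                             cfg$beta_sports * zsp) &&
                     !is.null(sport_by_cell[[cell]])) {
            pk <- sport_by_cell[[cell]]
            pk <- pk[sample.int(length(pk), 1L)]
            stop_lat <- city$pois$lat[pk] + stats::rnorm(1L, 0, 5 * deg_lat)
            stop_lon <- city$pois$lon[pk] + stats::rnorm(1L, 0, 5 * deg_lon)
            dwell_min <- stats::runif(1L, 12, 20)
          }
          w <- .seg_walk(t_cur, cur_lat, cur_lon, stop_lat, stop_lon,
                         cfg$walk_speed_ms, interval)
          segs[[length(segs) + 1L]] <- w$fix
          t_dwell_end <- w$t_end + dwell_min * 60
          segs[[length(segs) + 1L]] <-
            .seg_stationary(w$t_end + interval, t_dwell_end, stop_lat,
                            stop_lon, interval, .ctx_seg["dwell"])
          cur_lat <- stop_lat; cur_lon <- stop_lon
          t_cur <- t_dwell_end
        }
      }
      w <- .seg_walk(t_cur, cur_lat, cur_lon, ch$home_lat, ch$home_lon,
                     cfg$walk_speed_ms, interval)
      segs[[length(segs) + 1L]] <- w$fix
      segs[[length(segs) + 1L]] <-
        .seg_stationary(w$t_end + interval,
                        max(w$t_end + interval, 61200), ch$home_lat,
                        ch$home_lon, interval, .ctx_seg["home"])
      day <- do.call(rbind, segs)
      day <- day[order(day[, "t"]), , drop = FALSE]
      n <- nrow(day)
      # step increments: context rate x elapsed time, Poisson noise
      dt_h <- c(interval, diff(day[, "t"])) / 3600
      dt_h <- pmin(dt_h, interval * 2 / 3600) # an outage accrues no steps
      rate <- cfg$base_step_rate * .ctx_mult[day[, "ctx"]] * ch$rate_mult
      if (is_after[di]) rate <- rate * shift_after
      steps <- stats::rpois(n, rate * dt_h)
      keep <- stats::runif(n) >= cfg$dropout
      if (!any(keep)) next
      k <- k + 1L
      out[[k]] <- cbind(child = i, t = day0 + day[keep, "t"],
                        lat = day[keep, "lat"] +
                          stats::rnorm(sum(keep), 0, cfg$jitter_m * deg_lat),
                        lon = day[keep, "lon"] +
                          stats::rnorm(sum(keep), 0, cfg$jitter_m * deg_lon),
                        steps = steps[keep])
    }
  }
  if (k == 0L) {
    return(data.frame(child_id = character(0),
                      t = as.POSIXct(character(0), tz = "UTC"),
                      lat = numeric(0), lon = numeric(0),
                      steps = numeric(0), stringsAsFactors = FALSE))
  }
  m <- do.call(rbind, out[seq_len(k)])
  fixes <- data.frame(
    child_id = children$child_id[m[, "child"]],
    t = as.POSIXct(m[, "t"], origin = "1970-01-01", tz = "UTC"),
    lat = m[, "lat"], lon = m[, "lon"], steps = m[, "steps"],
    stringsAsFactors = FALSE
  )
  fixes <- fixes[order(fixes$child_id, fixes$t), , drop = FALSE]
  rownames(fixes) <- NULL
  fixes
}

#' Ground-truth tables of a simulated study
#'
#' Re-derives, independently of the trajectories, the quantities the
#' pipeline is supposed to recover: each child's true home cell and
#' municipality, the per-cell true POI counts and standardized
#' densities, and the configured after-period shift factors.
#'
#' @param cfg A [sim_config()].
#' @param city Output of [generate_city()].
#' @return A list: `homes` (child_id, cell, municipality), `cells`
#'   (per-cell POI counts and z-scores), `shift` (named numeric per
#'   municipality).
#' @export
ground_truth <- function(cfg, city) {
  ch <- generate_children(cfg, city)
  munis <- vapply(.muni_rectangles(cfg), `[[`, "", "name")
  shift <- stats::setNames(rep(1, length(munis)), munis)
  s <- cfg$activity_shift_after
  if (!is.null(s)) shift[names(s)] <- s
  list(homes = data.frame(child_id = ch$child_id, cell = ch$home_cell,
                          municipality = ch$municipality,
                          stringsAsFactors = FALSE),
       cells = city$cells,
       shift = shift)
}

#' Run the whole simulator
#'
#' @param cfg A [sim_config()].
#' @return A list: `config`, `city`, `children`, `fixes`, `truth`.
#' @export
simulate_study <- function(cfg) {
  city <- generate_city(cfg)
  children <- generate_children(cfg, city)
  fixes <- generate_cohort(cfg, city, children)
  list(config = cfg, city = city, children = children, fixes = fixes,
       truth = ground_truth(cfg, city))
}
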