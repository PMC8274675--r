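# Pipeline orchestration: the explore -> explain -> compare stages and
# the run manifest tying them together.

#' Build a pipeline configuration
#'
#' Collects the constants the analysis stages share. Defaults encode
#' the published analysis rules: precision-7 cells, 1-minute visit
#' eligibility (10 for sports-type percentages), the more-than-60-
#' minutes day rule, the more-than-5 suppression rule, the strict
#' 1000-m school radius, and the 30-m grid / 100-m radius density.
#'
#' @param precision Working geohash precision (6 or 7).
#' @param min_visit_min,min_sport_visit_min Visit duration filters,
#'   minutes.
#' @param max_gap_min Fix gap that splits a visit, minutes.
#' @param day_min Day-qualification threshold for resident daily
#'   steps, minutes (strictly greater than).
#' @param suppress_n Suppression threshold (publish only with more
#'   than this many contributions).
#' @param school_radius_m School-proximity radius, meters (strict).
#' @param grid_spacing_m,poi_radius_m Environment density lattice
#'   parameters, meters.
#' @param poi_contact_radius_m,poi_dwell_min POI contact detector:
#'   radius, meters, and minimum in-radius dwell, minutes.
#' @param night_window Nighttime hours used for residence assignment.
#' @param category_map Category-group mapping data.frame.
#' @param period_before,period_after Optional [period_spec()]s for the
#'   compare stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(precision = 7L, min_visit_min = 1,
                            min_sport_visit_min = 10, max_gap_min = 5,
                            day_min = 60, suppress_n = 5L,
                            school_radius_m = 1000, grid_spacing_m = 30,
                            poi_radius_m = 100, poi_contact_radius_m = 50,
                            poi_dwell_min = 1, night_window = c(0, 6),
                            category_map = default_category_map(),
                            period_before = NULL, period_after = NULL) {
  if (!precision %in% 1:12) stop("precision must be in 1..12", call. = FALSE)
  vals <- c(min_visit_min, min_sport_visit_min, max_gap_min, day_min,
            suppress_n, school_radius_m, grid_spacing_m, poi_radius_m,
            poi_contact_radius_m, poi_dwell_min)
  if (any(vals <= 0)) stop("thresholds must be positive", call. = FALSE)
  structure(list(precision = as.integer(precision),
                 min_visit_min = min_visit_min,
                 min_sport_visit_min = min_sport_visit_min,
                 max_gap_min = max_gap_min, day_min = day_min,
                 suppress_n = as.integer(suppress_n),
                 school_radius_m = school_radius_m,
                 grid_spacing_m = grid_spacing_m,
                 poi_radius_m = poi_radius_m,
                 poi_contact_radius_m = poi_contact_radius_m,
                 poi_dwell_min = poi_dwell_min,
                 night_window = night_window,
                 category_map = category_map,
                 period_before = period_before,
                 period_after = period_after),
            class = "pipeline_config")
}

.manifest <- function(config, inputs, counts) {
  digests <- lapply(inputs, function(p) {
    if (is.character(p) && file.exists(p)) {
      list(path = p, bytes = file.size(p))
    } else NULL
  })
  cfg <- config[setdiff(names(config), "category_map")]
  for (p in c("period_before", "period_after")) {
    if (!is.null(cfg[[p]])) {
      cfg[[p]] <- list(label = cfg[[p]]$label,
                       start = as.character(cfg[[p]]$start),
                       end = as.character(cfg[[p]]$end))
    }
  }
  list(tool = "obesogeo",
       version = as.character(utils::packageVersion("obesogeo")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
       config = cfg,
       inputs = digests,
       counts = counts)
}

.write_manifest <- function(manifest, out_dir) {
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null", POSIXt = "ISO8601")
  invisible(path)
}

#' Run the visit-extraction front end shared by the stages
#'
#' Validates fixes, segments visits at the working precision, attaches
#' POI contacts, and reports the filter accounting (visits dropped by
#' the duration filter vs. retained).
#'
#' @param fixes Fix data.frame.
#' @param pois POI data.frame (optional; without it no contact columns
#'   are attached).
#' @param config A [pipeline_config()].
#' @return A list: `visits`, `counts` (named list of stage counts).
#' @export
extract_visits <- function(fixes, pois = NULL,
                           config = pipeline_config()) {
  fixes <- validate_fixes(fixes)
  all_runs <- segment_visits(fixes, config$precision,
                             min_duration_min = 0,
                             max_gap_min = config$max_gap_min)
  visits <- all_runs[all_runs$duration_min >= config$min_visit_min, ,
                     drop = FALSE]
  rownames(visits) <- NULL
  if (!is.null(pois) && nrow(visits) > 0L) {
    visits <- attach_poi_contacts(visits, fixes, pois,
                                  config$poi_contact_radius_m,
                                  config$poi_dwell_min)
  }
  list(visits = visits,
       counts = list(n_fixes = nrow(fixes),
                     visits_in = nrow(all_runs),
                     visits_retained = nrow(visits),
                     visits_dropped_by_duration =
                       nrow(all_runs) - nrow(visits)))
}

#' Explore stage: indicator and environment tables
#'
#' Runs trajectory -> indicators and POI -> environment, applies the
#' suppression rule, and (when `out_dir` is given) writes
#' `indicators.csv/json`, `environment.csv/json` and `manifest.json`.
#'
#' @param fixes Fix data.frame (e.g. from [read_fixes()]).
#' @param pois POI data.frame.
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory.
#' @param density_categories Categories for the grid-radius density
#'   (default none here; it is an expensive per-cell lattice scan best
#'   requested explicitly).
#' @return A list: `indicators` (suppressed), `environment`, `visits`,
#'   `manifest`.
#' @export
run_explore <- function(fixes, pois, config = pipeline_config(),
                        out_dir = NULL, density_categories = character(0)) {
  ev <- extract_visits(fixes, pois, config)
  visits <- ev$visits
  residences <- assign_residence(fixes, config$precision,
                                 config$night_window)
  days <- summarize_days(fixes, config$max_gap_min)
  ind <- compute_indicators(visits, config$category_map, residences, days,
                            min_sport_visit_min = config$min_sport_visit_min)
  ind_pub <- suppress_low_support(ind, config$suppress_n)
  cells <- unique(ind_pub$region_id)
  env <- compute_environment(pois, cells, config$category_map,
                             density_categories,
                             config$grid_spacing_m, config$poi_radius_m)
  counts <- c(ev$counts,
              list(indicator_rows = nrow(ind),
                   rows_suppressed = attr(ind_pub, "n_suppressed"),
                   cells_published = length(cells)))
  manifest <- .manifest(config, list(), counts)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_table(ind_pub, file.path(out_dir, "indicators"))
    write_table(env, file.path(out_dir, "environment"))
    .write_manifest(manifest, out_dir)
  }
  list(indicators = ind_pub, environment = env, visits = visits,
       manifest = manifest)
}

#' Explain stage: behavior x environment associations near schools
#'
#' @param fixes,pois As in [run_explore()].
#' @param schools School data.frame.
#' @param config A [pipeline_config()].
#' @param pairing Pairing table (see [default_pairing()]).
#' @param out_dir Optional output directory (writes
#'   `associations.csv/json` and `manifest.json`).
#' @return A list: `associations`, `explore` (the underlying explore
#'   result), `manifest`.
#' @export
run_explain <- function(fixes, pois, schools, config = pipeline_config(),
                        pairing = default_pairing(), out_dir = NULL) {
  ex <- run_explore(fixes, pois, config)
  sel <- select_school_geohashes(unique(ex$indicators$region_id), schools,
                                 config$school_radius_m, config$precision)
  if (length(sel) == 0L) {
    warning("no school-proximal geohashes selected; empty report",
            call. = FALSE)
  }
  assoc <- associate(ex$indicators, ex$environment, schools, pairing,
                     radius_m = config$school_radius_m,
                     precision = config$precision)
  manifest <- .manifest(config, list(),
                        c(ex$manifest$counts,
                          list(school_proximal_cells = length(sel))))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_table(assoc, file.path(out_dir, "associations"))
    .write_manifest(manifest, out_dir)
  }
  list(associations = assoc, explore = ex, manifest = manifest)
}

#' Compare stage: municipality-level before/after report
#'
#' @param fixes Fix data.frame spanning both periods.
#' @param municipalities Municipality list.
#' @param config A [pipeline_config()] whose `period_before` and
#'   `period_after` are set (non-overlapping).
#' @param basis Aggregation basis for the step rate.
#' @param min_support Minimum distinct users per cell per period.
#' @param out_dir Optional output directory (writes
#'   `comparison.csv/json` and `manifest.json`).
#' @return A list: `comparison`, `manifest`.
#' @export
run_compare <- function(fixes, municipalities, config = pipeline_config(),
                        basis = "visits", min_support = 1L,
                        out_dir = NULL) {
  if (is.null(config$period_before) || is.null(config$period_after)) {
    stop("config error: both periods must be set for the compare stage",
         call. = FALSE)
  }
  .check_disjoint(config$period_before, config$period_after)
  ev <- extract_visits(fixes, pois = NULL, config)
  cmp <- compare_periods(ev$visits, municipalities,
                         config$period_before, config$period_after,
                         basis = basis, min_support = min_support)
  manifest <- .manifest(config, list(), ev$counts)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_table(cmp, file.path(out_dir, "comparison"))
    .write_manifest(manifest, out_dir)
  }
  list(comparison = cmp, manifest = manifest)
}

#' Simulate stage: write a synthetic study to disk
#'
#' Emits exactly the file formats the pipeline consumes - trajectory
#' CSV, POI CSV, schools CSV, municipalities GeoJSON - plus the
#' ground-truth tables (CSV).
#'
#' @param cfg A [sim_config()].
#' @param out_dir Output directory.
#' @return The [simulate_study()] result, invisibly.
#' @export
run_simulate <- function(cfg, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_study(cfg)
  write_fixes(sim$fixes, file.path(out_dir, "trajectory.csv"))
  utils::write.csv(sim$city$pois, file.path(out_dir, "pois.csv"),
                   row.names = FALSE)
  utils::write.csv(sim$city$schools, file.path(out_dir, "schools.csv"),
                   row.names = FALSE)
  write_municipalities(sim$city$municipalities,
                       file.path(out_dir, "municipalities.geojson"))
  utils::write.csv(sim$truth$homes, file.path(out_dir, "truth_homes.csv"),
                   row.names = FALSE)
  utils::write.csv(sim$truth$cells, file.path(out_dir, "truth_cells.csv"),
                   row.names = FALSE)
  invisible(sim)
}
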