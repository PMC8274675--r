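# Geohash-aggregated behavioral indicators.
#
# Three aggregation bases exist:
#   visits   - average over all stays in a cell, repeat visits counted;
#   visitors - each child's visits to the cell are pooled first, then
#              children are averaged (one vote per child);
#   residents- a child's behavior anywhere on the map, attributed to the
#              child's home cell.
# All means are unweighted over their basis. Cells are published only
# when more than `min_n` contributions exist (privacy suppression).

.empty_indicator <- function() {
  data.frame(region_id = character(0), indicator = character(0),
             basis = character(0), value = numeric(0),
             n_contributors = integer(0), stringsAsFactors = FALSE)
}

.indicator_row <- function(region, indicator, basis, value, n) {
  data.frame(region_id = region, indicator = indicator, basis = basis,
             value = value, n_contributors = as.integer(n),
             stringsAsFactors = FALSE)
}

#' Average steps per hour across visits, per cell
#'
#' Each eligible visit contributes its own steps/hour rate; the cell
#' value is the unweighted mean of those rates, so repeat visits by the
#' same child each count.
#'
#' @param visits Visit table (pre-filtered to duration >= 1 min by
#'   [segment_visits()]).
#' @return An indicator table (`region_id`, `indicator`, `basis`,
#'   `value`, `n_contributors`), one row per cell with at least one
#'   eligible visit.
#' @export
steps_per_hour_by_visits <- function(visits) {
  v <- visits[visits$duration_min > 0, , drop = FALSE]
  if (nrow(v) == 0L) return(.empty_indicator())
  rate <- v$steps / (v$duration_min / 60)
  m <- tapply(rate, v$cell, mean)
  n <- tapply(rate, v$cell, length)
  .indicator_row(names(m), "steps_per_hour", "visits",
                 as.vector(m), as.vector(n))
}

#' Average steps per hour across unique visitors, per cell
#'
#' Each child's visits to the cell are pooled first (total steps over
#' total time), then the cell value is the unweighted mean of the
#' per-child rates. Differs from the by-visits basis whenever children
#' make visits of unequal duration.
#'
#' @inheritParams steps_per_hour_by_visits
#' @return An indicator table, one row per cell; `n_contributors`
#'   counts unique children.
#' @export
steps_per_hour_by_visitors <- function(visits) {
  v <- visits[visits$duration_min > 0, , drop = FALSE]
  if (nrow(v) == 0L) return(.empty_indicator())
  key <- paste(v$cell, v$child_id, sep = "\r")
  agg <- rowsum(cbind(steps = v$steps, hours = v$duration_min / 60), key)
  cell <- sub("\r.*$", "", rownames(agg))
  rate <- agg[, "steps"] / agg[, "hours"]
  m <- tapply(rate, cell, mean)
  n <- tapply(rate, cell, length)
  .indicator_row(names(m), "steps_per_hour", "visitors",
                 as.vector(m), as.vector(n))
}

.group_categories <- function(category_map, place_group) {
  cats <- as.character(category_map$category)
  if (place_group %in% category_map$group) {
    cats[category_map$group == place_group]
  } else if (place_group %in% cats) {
    place_group
  } else {
    stop("unknown place group or category: ", place_group, call. = FALSE)
  }
}

#' Percentage of visits that include contact with a place type, per cell
#'
#' Among visits at least `min_duration_min` long, the percentage that
#' include at least one POI contact of the requested place group (a
#' whole group such as `"food"`, or a single category such as
#' `"fast_food"`). Food-type percentages use the 1-minute eligibility
#' filter, sports-type ones the 10-minute filter.
#'
#' @param visits Visit table with `contacts_<category>` columns from
#'   [attach_poi_contacts()].
#' @param place_group A group name from the category map or a single
#'   POI category name.
#' @param category_map Category-group mapping data.frame (`category`,
#'   `group`), see [default_category_map()].
#' @param min_duration_min Visit eligibility filter, minutes.
#' @param indicator Name used in the output table (defaults to
#'   `pct_visits_<place_group>`).
#' @return An indicator table on the `visits` basis; `n_contributors`
#'   counts eligible visits.
#' @export
pct_visits_with_place <- function(visits, place_group, category_map,
                                  min_duration_min = 1,
                                  indicator = paste0("pct_visits_",
                                                     place_group)) {
  cats <- .group_categories(category_map, place_group)
  cols <- paste0("contacts_", cats)
  cols <- cols[cols %in% names(visits)]
  v <- visits[visits$duration_min >= min_duration_min, , drop = FALSE]
  if (nrow(v) == 0L) return(.empty_indicator())
  hit <- if (length(cols)) {
    rowSums(as.matrix(v[cols]), na.rm = TRUE) >= 1
  } else {
    rep(FALSE, nrow(v))
  }
  m <- tapply(hit, v$cell, function(z) 100 * mean(z))
  n <- tapply(hit, v$cell, length)
  .indicator_row(names(m), indicator, "visits", as.vector(m), as.vector(n))
}

#' Average daily steps of residents, per home cell
#'
#' For each resident, the mean daily step count over days with more
#' than `min_recorded_min` minutes of recorded data (days with less
#' wear time are discarded); the cell value is the unweighted mean over
#' residents of the cell. The behavior itself may have happened
#' anywhere on the map - only the attribution is to the home cell.
#'
#' @param residences Output of [assign_residence()].
#' @param day_summaries Output of [summarize_days()].
#' @param min_recorded_min Day-qualification threshold, minutes
#'   (strictly greater than; default 60).
#' @return An indicator table on the `residents` basis;
#'   `n_contributors` counts residents with at least one qualifying
#'   day.
#' @export
daily_steps_residents <- function(residences, day_summaries,
                                  min_recorded_min = 60) {
  res <- residences[!is.na(residences$cell), , drop = FALSE]
  d <- day_summaries[day_summaries$recorded_min > min_recorded_min, ,
                     drop = FALSE]
  if (nrow(res) == 0L || nrow(d) == 0L) return(.empty_indicator())
  per_child <- tapply(d$steps, d$child_id, mean)
  res$daily <- per_child[res$child_id]
  res <- res[!is.na(res$daily), , drop = FALSE]
  if (nrow(res) == 0L) return(.empty_indicator())
  m <- tapply(res$daily, res$cell, mean)
  n <- tapply(res$daily, res$cell, length)
  .indicator_row(names(m), "daily_steps", "residents",
                 as.vector(m), as.vector(n))
}

#' Privacy suppression of low-support aggregates
#'
#' Retains only indicator rows whose contributor count (on the row's
#' own basis: visits, unique visitors, or residents) is strictly
#' greater than `min_n`. The number of suppressed rows is recorded in
#' the `"n_suppressed"` attribute.
#'
#' @param values Indicator table.
#' @param min_n Suppression threshold; a row needs more than `min_n`
#'   contributions to be published (default 5).
#' @return The filtered table, original row order preserved.
#' @export
suppress_low_support <- function(values, min_n = 5L) {
  keep <- values$n_contributors > min_n
  out <- values[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_suppressed") <- sum(!keep)
  out
}

#' Compute the full behavioral indicator table
#'
#' Runs all built-in indicators on one cohort: steps/hour on the visits
#' and visitors bases, the six visit-percentage indicators (food-related
#' overall, fast food/takeaway, supermarket/grocery with the 1-minute
#' filter; athletics/sports, indoor recreation, public park with the
#' 10-minute filter), and residents' average daily steps when
#' `residences` and `day_summaries` are supplied.
#'
#' @param visits Visit table with contact columns.
#' @param category_map Category-group mapping.
#' @param residences,day_summaries Optional inputs for the residents
#'   indicator.
#' @param min_sport_visit_min Eligibility filter for sports-type
#'   percentages, minutes (default 10).
#' @return A long indicator table.
#' @export
compute_indicators <- function(visits, category_map = default_category_map(),
                               residences = NULL, day_summaries = NULL,
                               min_sport_visit_min = 10) {
  food_groups <- list(
    food_related = "food",
    fast_food = "fast_food",
    supermarket = "supermarket"
  )
  sport_groups <- list(
    sports_facility = "sports_facility",
    indoor_recreation = "indoor_recreation",
    public_park = "public_park"
  )
  parts <- list(
    steps_per_hour_by_visits(visits),
    steps_per_hour_by_visitors(visits)
  )
  for (nm in names(food_groups)) {
    parts[[length(parts) + 1L]] <- pct_visits_with_place(
      visits, food_groups[[nm]], category_map, min_duration_min = 1,
      indicator = paste0("pct_visits_", nm))
  }
  for (nm in names(sport_groups)) {
    parts[[length(parts) + 1L]] <- pct_visits_with_place(
      visits, sport_groups[[nm]], category_map,
      min_duration_min = min_sport_visit_min,
      indicator = paste0("pct_visits_", nm))
  }
  if (!is.null(residences) && !is.null(day_summaries)) {
    parts[[length(parts) + 1L]] <- daily_steps_residents(residences,
                                                         day_summaries)
  }
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}
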