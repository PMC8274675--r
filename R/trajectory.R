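# Trajectory ingestion and visit segmentation.
#
# A "fix" is one timestamped GPS sample with the steps accrued since the
# child's previous fix. A "visit" is a maximal contiguous stay of one
# child inside one geohash cell; a time gap larger than max_gap_min
# between consecutive fixes ends a visit even within one cell, so that
# sparse sampling cannot fabricate long stays.

.parse_iso8601 <- function(x) {
  x <- sub("Z$", "", x)
  x <- sub("T", " ", x, fixed = TRUE)
  as.POSIXct(x, tz = "UTC",
             tryFormats = c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M",
                            "%Y-%m-%d"))
}

#' Read a trajectory CSV of per-child GPS fixes
#'
#' Expects columns `child_id,timestamp,lat,lon,steps` with ISO-8601
#' timestamps and `steps` the non-negative count accrued since the
#' child's previous fix. Rows are validated and sorted by
#' (child, time). With `strict = FALSE` (the default) invalid rows are
#' skipped with a warning naming their line numbers; with
#' `strict = TRUE` the first invalid row aborts the read.
#'
#' @param path Path to the CSV file.
#' @param strict Abort on the first invalid row instead of skipping.
#' @return A data.frame of fixes: `child_id`, `t` (POSIXct UTC), `lat`,
#'   `lon`, `steps`.
#' @export
read_fixes <- function(path, strict = FALSE) {
  if (!file.exists(path)) {
    stop("trajectory file not found: ", path, call. = FALSE)
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("child_id", "timestamp", "lat", "lon", "steps")
  if (!all(need %in% names(raw))) {
    stop("trajectory CSV must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  validate_fixes(data.frame(
    child_id = raw$child_id,
    t = .parse_iso8601(raw$timestamp),
    lat = suppressWarnings(as.numeric(raw$lat)),
    lon = suppressWarnings(as.numeric(raw$lon)),
    steps = suppressWarnings(as.numeric(raw$steps)),
    stringsAsFactors = FALSE
  ), strict = strict, line_offset = 1L)
}

#' Validate and sort a fix table
#'
#' Applies the row-level validity rules (parsable timestamp, in-range
#' coordinates, non-negative steps, no duplicate timestamps per child)
#' and returns the fixes sorted by (child_id, t).
#'
#' @param fixes Data.frame with columns `child_id`, `t`, `lat`, `lon`,
#'   `steps`.
#' @param strict Abort on the first invalid row instead of skipping.
#' @param line_offset Added to row indices in messages (1 for a CSV with
#'   a header line).
#' @return The validated, sorted fix data.frame.
#' @export
validate_fixes <- function(fixes, strict = FALSE, line_offset = 0L) {
  n <- nrow(fixes)
  if (n == 0L) return(fixes)
  bad <- is.na(fixes$t) | !is.finite(fixes$lat) | !is.finite(fixes$lon) |
    !is.finite(fixes$steps) |
    fixes$lat < -90 | fixes$lat > 90 |
    fixes$lon < -180 | fixes$lon >= 180 |
    fixes$steps < 0 | is.na(fixes$child_id) | fixes$child_id == ""
  if (any(bad)) {
    lines <- which(bad) + line_offset
    msg <- paste0("invalid fix row(s) at line ",
                  paste(utils::head(lines, 5L), collapse = ", "),
                  if (sum(bad) > 5L) sprintf(" (and %d more)", sum(bad) - 5L))
    if (strict) stop(msg, call. = FALSE)
    warning(msg, "; skipped", call. = FALSE)
    fixes <- fixes[!bad, , drop = FALSE]
  }
  dup <- duplicated(paste(fixes$child_id, as.numeric(fixes$t)))
  if (any(dup)) {
    lines <- which(dup) + line_offset
    msg <- paste0("duplicate timestamp for a child at line ",
                  paste(utils::head(lines, 5L), collapse = ", "))
    if (strict) stop(msg, call. = FALSE)
    warning(msg, "; skipped", call. = FALSE)
    fixes <- fixes[!dup, , drop = FALSE]
  }
  fixes <- fixes[order(fixes$child_id, fixes$t), , drop = FALSE]
  rownames(fixes) <- NULL
  fixes$steps <- as.numeric(fixes$steps)
  fixes
}

#' Segment fixes into geohash visits
#'
#' Maximal runs of consecutive fixes of one child that encode to the
#' same geohash cell form candidate visits; a gap longer than
#' `max_gap_min` between consecutive fixes splits a run; candidates
#' shorter than `min_duration_min` are dropped. Visit steps are the sum
#' of the step increments of all fixes after the first fix of the run
#' (a fix's increment belongs to the interval ending at that fix, so the
#' entry fix contributes nothing to the visit).
#'
#' @param fixes Validated fix data.frame (may hold several children).
#' @param precision Geohash precision of the working cells (usually 6
#'   or 7).
#' @param min_duration_min Minimum visit duration in minutes (default 1,
#'   the eligibility rule for step-rate and food-place indicators).
#' @param max_gap_min Maximum tolerated gap between consecutive fixes of
#'   one visit, minutes.
#' @return A data.frame of visits: `child_id`, `cell`, `t_entry`,
#'   `t_exit`, `duration_min`, `steps`, `n_fixes`, `row_start`,
#'   `row_end` (row indices into the sorted input, used to recover the
#'   constituent fixes for POI contact detection).
#' @export
segment_visits <- function(fixes, precision = 7L, min_duration_min = 1,
                           max_gap_min = 5) {
  empty <- data.frame(child_id = character(0), cell = character(0),
                      t_entry = as.POSIXct(character(0), tz = "UTC"),
                      t_exit = as.POSIXct(character(0), tz = "UTC"),
                      duration_min = numeric(0), steps = numeric(0),
                      n_fixes = integer(0), row_start = integer(0),
                      row_end = integer(0), stringsAsFactors = FALSE)
  if (nrow(fixes) == 0L) return(empty)
  o <- order(fixes$child_id, fixes$t)
  fixes <- fixes[o, , drop = FALSE]
  cell <- geohash_encode(fixes$lat, fixes$lon, precision)
  tt <- as.numeric(fixes$t)
  n <- nrow(fixes)
  new_run <- c(TRUE,
               fixes$child_id[-1L] != fixes$child_id[-n] |
                 cell[-1L] != cell[-n] |
                 (tt[-1L] - tt[-n]) > max_gap_min * 60)
  run <- cumsum(new_run)
  first <- which(new_run)
  last <- c(first[-1L] - 1L, n)
  run_steps <- as.vector(rowsum(fixes$steps, run)) - fixes$steps[first]
  out <- data.frame(
    child_id = fixes$child_id[first],
    cell = cell[first],
    t_entry = fixes$t[first],
    t_exit = fixes$t[last],
    duration_min = (tt[last] - tt[first]) / 60,
    steps = run_steps,
    n_fixes = last - first + 1L,
    row_start = first,
    row_end = last,
    stringsAsFactors = FALSE
  )
  out <- out[out$duration_min >= min_duration_min, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "fixes_order") <- o
  out
}

#' Count POI contacts for each visit
#'
#' For every visit, the time during which consecutive constituent fixes
#' lie within `contact_radius_m` of a POI is accumulated per POI; a
#' contact is recorded when that dwell time reaches `min_dwell_min`.
#' Contacts are tallied per POI category and appended to the visit table
#' as integer columns `contacts_<category>`.
#'
#' @param visits Visit table from [segment_visits()] (its `row_start` /
#'   `row_end` must refer to `fixes` sorted by (child, time)).
#' @param fixes The same sorted fix table the visits were built from.
#' @param pois POI data.frame: `id`, `category`, `lat`, `lon`.
#' @param contact_radius_m Contact radius in meters (default 50).
#' @param min_dwell_min Minimum in-radius dwell for a contact, minutes
#'   (default 1).
#' @return The visit table with one `contacts_<category>` column per POI
#'   category (all categories present in `pois`, zero-filled).
#' @export
attach_poi_contacts <- function(visits, fixes, pois,
                                contact_radius_m = 50, min_dwell_min = 1) {
  cats <- sort(unique(as.character(pois$category)))
  for (cat in cats) {
    visits[[paste0("contacts_", cat)]] <- rep(0L, nrow(visits))
  }
  if (nrow(visits) == 0L || nrow(pois) == 0L) return(visits)
  o <- order(fixes$child_id, fixes$t)
  fixes <- fixes[o, , drop = FALSE]
  tt <- as.numeric(fixes$t)
  # degree half-window for the candidate-POI box filter; the 400-m
  # cushion covers the extent of a visit around its entry fix (visits
  # never span more than one precision-6/7 cell, plus GPS noise)
  dlat <- (contact_radius_m + 400) / 111320
  poi_lat <- pois$lat; poi_lon <- pois$lon
  poi_cat <- as.character(pois$category)
  lat_order <- order(pois$lat)
  slat <- pois$lat[lat_order]
  for (i in seq_len(nrow(visits))) {
    clat <- fixes$lat[visits$row_start[i]]
    clon <- fixes$lon[visits$row_start[i]]
    lo <- findInterval(clat - dlat, slat)
    hi <- findInterval(clat + dlat, slat)
    if (hi <= lo) next
    cand <- lat_order[(lo + 1L):hi]
    dlon <- dlat / max(cos(clat * pi / 180), 0.05)
    cand <- cand[abs(pois$lon[cand] - clon) < dlon]
    if (length(cand) == 0L) next
    rows <- visits$row_start[i]:visits$row_end[i]
    ft <- tt[rows]
    # time credited to a fix: half of each adjacent inter-fix interval
    dt <- diff(ft)
    w <- (c(0, dt) + c(dt, 0)) / 2
    for (k in cand) {
      d <- haversine_m(fixes$lat[rows], fixes$lon[rows],
                       poi_lat[k], poi_lon[k])
      dwell_s <- sum(w[d <= contact_radius_m])
      if (dwell_s >= min_dwell_min * 60) {
        col <- paste0("contacts_", poi_cat[k])
        visits[[col]][i] <- visits[[col]][i] + 1L
      }
    }
  }
  visits
}

#' Per-day recorded time and step totals
#'
#' Summarizes each child's fixes per UTC calendar day: `recorded_min` is
#' the sum of inter-fix intervals, each capped at `max_gap_min` (so a
#' long outage does not count as recorded wear time), and `steps` is the
#' sum of the day's step increments.
#'
#' @param fixes Validated fix data.frame.
#' @param max_gap_min Per-interval cap, minutes.
#' @param tz_offset_hours Hours added to UTC before assigning the
#'   calendar day (default 0, i.e. UTC days).
#' @return A data.frame: `child_id`, `date` (Date), `recorded_min`,
#'   `steps`.
#' @export
summarize_days <- function(fixes, max_gap_min = 5, tz_offset_hours = 0) {
  empty <- data.frame(child_id = character(0),
                      date = as.Date(character(0)),
                      recorded_min = numeric(0), steps = numeric(0),
                      stringsAsFactors = FALSE)
  if (nrow(fixes) == 0L) return(empty)
  fixes <- fixes[order(fixes$child_id, fixes$t), , drop = FALSE]
  tt <- as.numeric(fixes$t) + tz_offset_hours * 3600
  day <- as.Date(floor(tt / 86400), origin = "1970-01-01")
  n <- nrow(fixes)
  same <- c(FALSE, fixes$child_id[-1L] == fixes$child_id[-n] &
              day[-1L] == day[-n])
  gap_min <- c(0, (tt[-1L] - tt[-n]) / 60)
  rec <- ifelse(same, pmin(gap_min, max_gap_min), 0)
  key <- paste(fixes$child_id, day)
  agg <- rowsum(cbind(rec = rec, steps = fixes$steps), key)
  first <- !duplicated(key)
  out <- data.frame(child_id = fixes$child_id[first],
                    date = day[first],
                    stringsAsFactors = FALSE)
  ord <- match(paste(out$child_id, out$date), rownames(agg))
  out$recorded_min <- agg[ord, "rec"]
  out$steps <- agg[ord, "steps"]
  out <- out[order(out$child_id, out$date), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign each child a residence geohash
#'
#' The residence is the cell holding the maximum total recorded time
#' during the nighttime window (default 00:00-06:00 UTC), with ties
#' broken toward the lexicographically smaller code. Children with no
#' nighttime fixes get `NA` and are excluded from resident-based
#' indicators.
#'
#' @param fixes Validated fix data.frame.
#' @param precision Geohash precision of the residence cell.
#' @param night_window Two-element numeric, start and end hour of the
#'   nighttime window.
#' @param max_gap_min Per-interval cap used when accumulating nighttime
#'   recorded time, minutes.
#' @return A data.frame: `child_id`, `cell` (NA when undefined).
#' @export
assign_residence <- function(fixes, precision = 7L,
                             night_window = c(0, 6), max_gap_min = 35) {
  children <- sort(unique(fixes$child_id))
  out <- data.frame(child_id = children, cell = NA_character_,
                    stringsAsFactors = FALSE)
  if (nrow(fixes) == 0L) return(out)
  fixes <- fixes[order(fixes$child_id, fixes$t), , drop = FALSE]
  tt <- as.numeric(fixes$t)
  hour <- (tt %% 86400) / 3600
  night <- hour >= night_window[1L] & hour < night_window[2L]
  n <- nrow(fixes)
  cell_all <- geohash_encode(fixes$lat, fixes$lon, precision)
  # an interval is credited to a cell only when both its endpoint fixes
  # of the same child lie in that cell and the interval ends at night
  same <- c(FALSE, fixes$child_id[-1L] == fixes$child_id[-n] &
              cell_all[-1L] == cell_all[-n])
  w <- c(0, pmin((tt[-1L] - tt[-n]) / 60, max_gap_min))
  w[!same] <- 0
  keep <- night & w > 0
  if (!any(keep)) return(out)
  cell <- cell_all[keep]
  agg <- rowsum(w[keep], paste(fixes$child_id[keep], cell, sep = "\r"))
  key <- do.call(rbind, strsplit(rownames(agg), "\r", fixed = TRUE))
  res <- data.frame(child_id = key[, 1L], cell = key[, 2L],
                    minutes = as.vector(agg), stringsAsFactors = FALSE)
  res <- res[order(res$child_id, -res$minutes, res$cell), , drop = FALSE]
  res <- res[!duplicated(res$child_id), , drop = FALSE]
  out$cell <- res$cell[match(out$child_id, res$child_id)]
  out
}
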