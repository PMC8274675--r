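# Municipality-level before/after comparison of a behavior.

#' Define a comparison period
#'
#' @param label Period label, e.g. `"before"` or `"after"`.
#' @param start,end Inclusive calendar dates (anything
#'   [as.Date()]-able).
#' @return A `period_spec` list: `label`, `start`, `end`.
#' @export
period_spec <- function(label, start, end) {
  start <- as.Date(start); end <- as.Date(end)
  if (is.na(start) || is.na(end)) stop("unparsable period date", call. = FALSE)
  if (start > end) stop("period start after end", call. = FALSE)
  structure(list(label = label, start = start, end = end),
            class = "period_spec")
}

.check_disjoint <- function(a, b) {
  if (a$start <= b$end && b$start <= a$end) {
    stop("periods overlap: ", a$label, " and ", b$label, call. = FALSE)
  }
  invisible(TRUE)
}

#' Assign geohash cells to municipalities
#'
#' A cell belongs to the first municipality (in input order) whose
#' boundary contains the cell's center, so a center lying exactly on a
#' shared border is assigned to exactly one municipality.
#'
#' @param cells Character vector of geohash codes.
#' @param municipalities List of municipalities, each a list with
#'   `name` and `rings` (a list of closed lon/lat matrices, outer ring
#'   first), e.g. from [read_municipalities()].
#' @return Character vector of municipality names (NA when the center
#'   falls in none), parallel to `cells`.
#' @export
cells_in_municipality <- function(cells, municipalities) {
  if (length(cells) == 0L) return(character(0))
  ctr <- geohash_decode(cells)
  assigned <- rep(NA_character_, length(cells))
  for (m in municipalities) {
    todo <- is.na(assigned)
    if (!any(todo)) break
    inside <- point_in_polygon(ctr$lat[todo], ctr$lon[todo], m$rings)
    assigned[todo][inside] <- m$name
  }
  assigned
}

#' Per-cell behavior values of a municipality in one period
#'
#' Filters visits to the period (membership decided by the visit's
#' entry timestamp), computes the per-cell behavior, and keeps the
#' cells of the municipality where at least `min_support` distinct
#' users contributed. Note the default is 1 user - the monitoring
#' dashboards' stricter more-than-5 suppression rule is a separate,
#' independent threshold.
#'
#' @param visits Visit table for the whole study span.
#' @param municipality Municipality name.
#' @param muni_of Named character vector mapping cell -> municipality
#'   (from [cells_in_municipality()]).
#' @param period A [period_spec()].
#' @param basis `"visits"` or `"visitors"` aggregation for the step
#'   rate.
#' @param min_support Minimum distinct users per cell (default 1).
#' @return Numeric vector of per-cell values, named by cell.
#' @export
municipal_series <- function(visits, municipality, muni_of, period,
                             basis = c("visits", "visitors"),
                             min_support = 1L) {
  basis <- match.arg(basis)
  day <- as.Date(visits$t_entry, tz = "UTC")
  v <- visits[day >= period$start & day <= period$end, , drop = FALSE]
  v <- v[!is.na(muni_of[v$cell]) & muni_of[v$cell] == municipality, ,
         drop = FALSE]
  if (nrow(v) == 0L) return(stats::setNames(numeric(0), character(0)))
  ind <- if (basis == "visits") steps_per_hour_by_visits(v) else
    steps_per_hour_by_visitors(v)
  users <- tapply(v$child_id, v$cell, function(z) length(unique(z)))
  ok <- names(users)[users >= min_support]
  ind <- ind[ind$region_id %in% ok, , drop = FALSE]
  stats::setNames(ind$value, ind$region_id)
}

#' Welch's two-sample t test
#'
#' Unequal-variance two-sample t statistic with Welch-Satterthwaite
#' degrees of freedom and a two-sided p-value.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @return A list: `t`, `df`, `p`, `mean_a`, `mean_b`, `n_a`, `n_b`.
#' @export
welch_t_test <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L) {
    stop("insufficient data: each sample needs n >= 2", call. = FALSE)
  }
  va <- stats::var(a); vb <- stats::var(b)
  se2 <- va / na + vb / nb
  if (se2 == 0) {
    stop("zero variance in both samples", call. = FALSE)
  }
  tstat <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(tstat), df = df)
  list(t = tstat, df = df, p = p, mean_a = mean(a), mean_b = mean(b),
       n_a = na, n_b = nb)
}

#' Compare a behavior between two periods across municipalities
#'
#' For each municipality (plus a pooled `"Total"` row) the per-cell
#' step rates of the before and after periods are compared with
#' Welch's t test (or the pooled-variance Student test). Cells are
#' counted per period; a municipality lacking enough cells in either
#' period is flagged, not dropped.
#'
#' @param visits Visit table spanning both periods.
#' @param municipalities Municipality list (see
#'   [cells_in_municipality()]).
#' @param before,after [period_spec()] objects; must not overlap.
#' @param basis Aggregation basis for the step rate.
#' @param min_support Minimum distinct users per cell per period.
#' @param var_equal Use the pooled-variance Student test instead of
#'   Welch (default FALSE).
#' @return Data.frame: `municipality`, `n_cells_before`,
#'   `mean_before`, `n_cells_after`, `mean_after`, `t`, `df`, `p`,
#'   `note`.
#' @export
compare_periods <- function(visits, municipalities, before, after,
                            basis = "visits", min_support = 1L,
                            var_equal = FALSE) {
  .check_disjoint(before, after)
  cells <- unique(visits$cell)
  muni_of <- stats::setNames(cells_in_municipality(cells, municipalities),
                             cells)
  names_m <- c(vapply(municipalities, `[[`, "", "name"), "Total")
  out <- list()
  all_a <- list(); all_b <- list()
  for (m in names_m) {
    if (m == "Total") {
      a <- unlist(all_b, use.names = FALSE)
      b <- unlist(all_a, use.names = FALSE)
    } else {
      a <- municipal_series(visits, m, muni_of, before, basis, min_support)
      b <- municipal_series(visits, m, muni_of, after, basis, min_support)
      all_b[[m]] <- a; all_a[[m]] <- b
    }
    row <- data.frame(municipality = m,
                      n_cells_before = length(a),
                      mean_before = if (length(a)) mean(a) else NA_real_,
                      n_cells_after = length(b),
                      mean_after = if (length(b)) mean(b) else NA_real_,
                      t = NA_real_, df = NA_real_, p = NA_real_,
                      note = "", stringsAsFactors = FALSE)
    if (length(a) < 2L || length(b) < 2L) {
      row$note <- "not computable (fewer than 2 cells in a period)"
    } else if (var_equal) {
      fit <- stats::t.test(a, b, var.equal = TRUE)
      row$t <- unname(fit$statistic); row$df <- unname(fit$parameter)
      row$p <- fit$p.value
    } else if (stats::var(a) + stats::var(b) == 0) {
      row$note <- "not computable (zero variance in both periods)"
    } else {
      fit <- welch_t_test(a, b)
      row$t <- fit$t; row$df <- fit$df; row$p <- fit$p
    }
    out[[length(out) + 1L]] <- row
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
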