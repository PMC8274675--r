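# Behavior x environment associations in school-proximal geohashes.

#' Select geohashes close to schools
#'
#' Keeps the cells whose center lies strictly less than `radius_m` from
#' at least one school; a cell near several schools appears once.
#'
#' @param cells Character vector of geohash codes (precision 7 by
#'   convention for this analysis; enforced via `precision`).
#' @param schools Data.frame with `lat`, `lon` (and optionally `id`,
#'   `city`).
#' @param radius_m Selection radius in meters, strict inequality
#'   (default 1000).
#' @param precision Required precision of `cells`; `NULL` disables the
#'   check.
#' @return The selected subset of `cells`, input order preserved.
#' @export
select_school_geohashes <- function(cells, schools, radius_m = 1000,
                                    precision = 7L) {
  if (length(cells) == 0L) return(character(0))
  .gh_validate_codes(cells)
  if (!is.null(precision) && any(nchar(cells) != precision)) {
    stop("cells must be at precision ", precision, call. = FALSE)
  }
  ctr <- geohash_decode(cells)
  keep <- rep(FALSE, length(cells))
  for (i in seq_len(nrow(schools))) {
    d <- haversine_m(ctr$lat, ctr$lon, schools$lat[i], schools$lon[i])
    keep <- keep | (d < radius_m)
  }
  unique(cells[keep])
}

#' Pearson correlation with Fisher-z CI and t-based p-value
#'
#' r = cov(x, y) / (sd(x) sd(y)) with the sample (n-1) covariance; the
#' two-sided p-value comes from t = r sqrt((n-2)/(1-r^2)) against the
#' t distribution with n-2 degrees of freedom; the confidence interval
#' from the Fisher z-transform, tanh(atanh(r) +/- z* / sqrt(n-3)).
#'
#' @param x,y Numeric vectors of equal length, n >= 3, each with
#'   non-zero variance.
#' @param conf_level Confidence level for the Fisher-z interval.
#' @return A list: `r`, `ci_low`, `ci_high`, `p`, `n`.
#' @export
pearson_test <- function(x, y, conf_level = 0.95) {
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("insufficient data: n < 3", call. = FALSE)
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0) {
    stop("undefined correlation: zero variance", call. = FALSE)
  }
  r <- stats::cov(x, y) / (sx * sy)
  r <- max(min(r, 1), -1)
  if (abs(r) < 1) {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  } else {
    p <- 0
  }
  zcrit <- stats::qnorm((1 + conf_level) / 2)
  if (n > 3L && abs(r) < 1) {
    z <- atanh(r)
    ci <- tanh(z + c(-1, 1) * zcrit / sqrt(n - 3))
  } else {
    ci <- c(NA_real_, NA_real_)
  }
  list(r = r, ci_low = ci[1L], ci_high = ci[2L], p = p, n = n)
}

#' Default behavior-characteristic pairing
#'
#' Step rates (both bases) are paired with the Food and Sports
#' composites; each visit-percentage indicator with the count of its
#' own place type (food-related visits with the Food composite, since
#' "food places" spans all food categories).
#'
#' @return Data.frame with columns `indicator`, `basis`,
#'   `characteristic`.
#' @export
default_pairing <- function() {
  data.frame(
    indicator = c("steps_per_hour", "steps_per_hour",
                  "steps_per_hour", "steps_per_hour",
                  "pct_visits_food_related", "pct_visits_fast_food",
                  "pct_visits_supermarket", "pct_visits_sports_facility",
                  "pct_visits_indoor_recreation", "pct_visits_public_park"),
    basis = c("visitors", "visitors", "visits", "visits",
              rep("visits", 6L)),
    characteristic = c("composite_food", "composite_sports",
                       "composite_food", "composite_sports",
                       "composite_food", "count_fast_food",
                       "count_supermarket", "count_sports_facility",
                       "count_indoor_recreation", "count_public_park"),
    stringsAsFactors = FALSE
  )
}

#' Behavior x environment correlation analysis near schools
#'
#' For each city and each (behavior, characteristic) pair, joins the
#' suppression-filtered indicator table with the environment table on
#' the school-proximal geohashes of that city's schools and computes
#' the Pearson correlation with CI and p-value. Pairs whose join yields
#' fewer than 3 cells, or a zero-variance side, are flagged in `note`
#' rather than dropped.
#'
#' @param indicators Indicator table (already passed through
#'   [suppress_low_support()] if the privacy rule is wanted).
#' @param env Environment table from [compute_environment()].
#' @param schools School data.frame (`id`, `lat`, `lon`, optional
#'   `city`).
#' @param pairing Pairing table, see [default_pairing()].
#' @param radius_m School-proximity radius, meters (strict; default
#'   1000).
#' @param precision Working geohash precision (default 7).
#' @param p_adjust Optional multiple-testing correction method passed
#'   to [stats::p.adjust()] (e.g. `"BH"`); `"none"` (default) reports
#'   raw per-pair p-values.
#' @return Data.frame: `city`, `behavior`, `basis`, `characteristic`,
#'   `n`, `r`, `ci_low`, `ci_high`, `p`, `note`.
#' @export
associate <- function(indicators, env, schools, pairing = default_pairing(),
                      radius_m = 1000, precision = 7L, p_adjust = "none") {
  if (is.null(schools$city)) schools$city <- "city"
  out <- list()
  for (city in unique(schools$city)) {
    sch <- schools[schools$city == city, , drop = FALSE]
    cells <- select_school_geohashes(unique(indicators$region_id), sch,
                                     radius_m, precision)
    for (j in seq_len(nrow(pairing))) {
      beh <- indicators[indicators$indicator == pairing$indicator[j] &
                          indicators$basis == pairing$basis[j] &
                          indicators$region_id %in% cells, , drop = FALSE]
      ev <- env[env$characteristic == pairing$characteristic[j], ,
                drop = FALSE]
      m <- match(beh$region_id, ev$cell)
      x <- beh$value[!is.na(m)]
      y <- ev$value[m[!is.na(m)]]
      row <- data.frame(city = city, behavior = pairing$indicator[j],
                        basis = pairing$basis[j],
                        characteristic = pairing$characteristic[j],
                        n = length(x), r = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, p = NA_real_, note = "",
                        stringsAsFactors = FALSE)
      if (length(x) < 3L) {
        row$note <- "insufficient data (n < 3)"
      } else if (stats::sd(x) == 0 || stats::sd(y) == 0) {
        row$note <- "undefined correlation (zero variance)"
      } else {
        fit <- pearson_test(x, y)
        row$r <- fit$r; row$ci_low <- fit$ci_low
        row$ci_high <- fit$ci_high; row$p <- fit$p
      }
      out[[length(out) + 1L]] <- row
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  if (!identical(p_adjust, "none")) {
    out$p_adjusted <- stats::p.adjust(out$p, method = p_adjust)
  }
  out
}
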