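# Independent oracles used across tests. These deliberately take a
# different computational route than the package implementation.

# Closed-form geohash encoding: integer bin indices of lon/lat computed
# directly, bits interleaved (lon first), 5 bits per character. No
# iterative bisection, unlike the implementation.
oracle_geohash <- function(lat, lon, precision) {
  alphabet <- strsplit("0123456789bcdefghjkmnpqrstuvwxyz", "")[[1]]
  vapply(seq_along(lat), function(i) {
    nb <- 5L * precision
    nlon <- ceiling(nb / 2)
    nlat <- floor(nb / 2)
    ilon <- min(floor((lon[i] + 180) / 360 * 2^nlon), 2^nlon - 1)
    ilat <- min(floor((lat[i] + 90) / 180 * 2^nlat), 2^nlat - 1)
    to_bits <- function(v, n) {
      out <- integer(n)
      for (k in n:1) {
        out[k] <- v %% 2
        v <- v %/% 2
      }
      out
    }
    bits <- integer(nb)
    bits[seq(1L, nb, by = 2L)] <- to_bits(ilon, nlon)
    bits[seq(2L, nb, by = 2L)] <- to_bits(ilat, nlat)
    paste(vapply(seq_len(precision), function(j) {
      v <- sum(bits[(5L * j - 4L):(5L * j)] * c(16L, 8L, 4L, 2L, 1L))
      alphabet[v + 1L]
    }, character(1)), collapse = "")
  }, character(1))
}

# Pearson r, t-based p and Fisher-z CI from explicit sums.
oracle_pearson <- function(x, y, conf_level = 0.95) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sxy <- sum((x - mx) * (y - my)) / (n - 1)
  sx <- sqrt(sum((x - mx)^2) / (n - 1))
  sy <- sqrt(sum((y - my)^2) / (n - 1))
  r <- sxy / (sx * sy)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  z <- 0.5 * log((1 + r) / (1 - r))
  zc <- stats::qnorm((1 + conf_level) / 2)
  lo <- z - zc / sqrt(n - 3)
  hi <- z + zc / sqrt(n - 3)
  list(r = r, p = p,
       ci_low = (exp(2 * lo) - 1) / (exp(2 * lo) + 1),
       ci_high = (exp(2 * hi) - 1) / (exp(2 * hi) + 1))
}

# Welch statistic, Welch-Satterthwaite df and two-sided p from the
# textbook formulas, with explicit sum-based moments.
oracle_welch <- function(a, b) {
  na <- length(a); nb <- length(b)
  ma <- sum(a) / na; mb <- sum(b) / nb
  va <- sum((a - ma)^2) / (na - 1)
  vb <- sum((b - mb)^2) / (nb - 1)
  tstat <- (ma - mb) / sqrt(va / na + vb / nb)
  df <- (va / na + vb / nb)^2 /
    ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(tstat), df = df)
  list(t = tstat, df = df, p = p)
}
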