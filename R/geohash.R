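# Geohash spatial primitives.
#
# Standard public geohash: interleaved binary subdivision of the
# (lon, lat) plane, longitude bit first, 5 bits per base-32 character.
# Cell edges follow the half-open convention implied by the encoding
# itself (a point on the bisecting meridian/parallel falls in the
# upper half).

.gh_alphabet <- strsplit("0123456789bcdefghjkmnpqrstuvwxyz", "")[[1]]
.gh_digit <- local({
  d <- seq_along(.gh_alphabet) - 1L
  names(d) <- .gh_alphabet
  d
})

.check_latlon <- function(lat, lon) {
  if (length(lat) != length(lon)) {
    stop("lat and lon must have equal length", call. = FALSE)
  }
  if (any(!is.finite(lat)) || any(!is.finite(lon))) {
    stop("non-finite coordinates", call. = FALSE)
  }
  if (any(lat < -90 | lat > 90)) {
    stop("latitude out of range [-90, 90]", call. = FALSE)
  }
  if (any(lon < -180 | lon >= 180)) {
    stop("longitude out of range [-180, 180)", call. = FALSE)
  }
  invisible(TRUE)
}

#' Encode coordinates as geohash codes
#'
#' Computes the standard base-32 geohash of each point at the requested
#' precision (number of characters). Longer codes denote smaller cells;
#' the code of a point at precision k+1 always has its precision-k code
#' as a prefix, which is what makes geohashes usable as a nested spatial
#' aggregation structure.
#'
#' @param lat,lon Numeric vectors of coordinates in decimal degrees
#'   (latitude in \[-90, 90\], longitude in \[-180, 180)).
#' @param precision Integer in 1..12, the number of base-32 characters.
#' @return Character vector of geohash codes, one per input point.
#' @examples
#' geohash_encode(57.64911, 10.40744, 7) # "u4pruyd"
#' @export
geohash_encode <- function(lat, lon, precision = 7L) {
  precision <- as.integer(precision)
  if (length(precision) != 1L || is.na(precision) ||
      precision < 1L || precision > 12L) {
    stop("precision must be a single integer in 1..12", call. = FALSE)
  }
  .check_latlon(lat, lon)
  n <- length(lat)
  if (n == 0L) return(character(0))

  lon_lo <- rep(-180, n); lon_hi <- rep(180, n)
  lat_lo <- rep(-90, n); lat_hi <- rep(90, n)
  nbits <- 5L * precision
  bits <- matrix(0L, nrow = n, ncol = nbits)
  for (i in seq_len(nbits)) {
    if (i %% 2L == 1L) { # odd bit: longitude
      mid <- (lon_lo + lon_hi) / 2
      hi <- lon >= mid
      lon_lo[hi] <- mid[hi]
      lon_hi[!hi] <- mid[!hi]
    } else {
      mid <- (lat_lo + lat_hi) / 2
      hi <- lat >= mid
      lat_lo[hi] <- mid[hi]
      lat_hi[!hi] <- mid[!hi]
    }
    bits[, i] <- as.integer(hi)
  }
  w <- c(16L, 8L, 4L, 2L, 1L)
  chars <- lapply(seq_len(precision), function(j) {
    val <- bits[, (5L * j - 4L):(5L * j), drop = FALSE] %*% w
    .gh_alphabet[val + 1L]
  })
  do.call(paste0, chars)
}

.gh_validate_codes <- function(code) {
  if (length(code) == 0L) return(invisible(TRUE))
  if (any(is.na(code)) || any(nchar(code) == 0L)) {
    stop("empty or missing geohash code", call. = FALSE)
  }
  if (any(nchar(code) > 12L)) {
    stop("geohash code longer than 12 characters", call. = FALSE)
  }
  bad <- !grepl("^[0123456789bcdefghjkmnpqrstuvwxyz]+$", code)
  if (any(bad)) {
    stop("invalid geohash character in: ",
         paste(utils::head(unique(code[bad]), 3L), collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Decode geohash codes to bounding boxes
#'
#' Inverts the geohash bit interleaving, returning the bounding box and
#' center of each cell. Codes of mixed precision are accepted.
#'
#' @param code Character vector of geohash codes.
#' @return A data.frame with columns `code`, `precision`, `south`,
#'   `west`, `north`, `east`, `lat`, `lon` (cell center).
#' @examples
#' geohash_decode("s") # box lat [0,45], lon [0,45]
#' @export
geohash_decode <- function(code) {
  .gh_validate_codes(code)
  n <- length(code)
  out <- data.frame(
    code = code, precision = nchar(code),
    south = numeric(n), west = numeric(n),
    north = numeric(n), east = numeric(n),
    lat = numeric(n), lon = numeric(n),
    stringsAsFactors = FALSE
  )
  if (n == 0L) return(out)
  for (p in unique(out$precision)) {
    idx <- which(out$precision == p)
    m <- matrix(unlist(strsplit(code[idx], ""), use.names = FALSE),
                nrow = length(idx), byrow = TRUE)
    lon_lo <- rep(-180, length(idx)); lon_hi <- rep(180, length(idx))
    lat_lo <- rep(-90, length(idx)); lat_hi <- rep(90, length(idx))
    bit_i <- 0L
    for (j in seq_len(p)) {
      val <- .gh_digit[m[, j]]
      for (b in 4:0) {
        bit_i <- bit_i + 1L
        hi <- bitwAnd(val, bitwShiftL(1L, b)) > 0L
        if (bit_i %% 2L == 1L) {
          mid <- (lon_lo + lon_hi) / 2
          lon_lo[hi] <- mid[hi]
          lon_hi[!hi] <- mid[!hi]
        } else {
          mid <- (lat_lo + lat_hi) / 2
          lat_lo[hi] <- mid[hi]
          lat_hi[!hi] <- mid[!hi]
        }
      }
    }
    out$south[idx] <- lat_lo; out$north[idx] <- lat_hi
    out$west[idx] <- lon_lo; out$east[idx] <- lon_hi
  }
  out$lat <- (out$south + out$north) / 2
  out$lon <- (out$west + out$east) / 2
  out
}

#' Physical dimensions of geohash cells
#'
#' Width is the great-circle length of the cell's mid-latitude parallel
#' segment, height the great-circle length of its meridian segment. A
#' 6-character cell at the equator measures about 1.22 km by 610 m and a
#' 7-character cell about 153 m by 153 m; width shrinks with the cosine
#' of latitude, height does not.
#'
#' @param code Character vector of geohash codes.
#' @return A data.frame with columns `code`, `width_m`, `height_m`.
#' @export
geohash_cell_dimensions <- function(code) {
  d <- geohash_decode(code)
  midlat <- (d$south + d$north) / 2
  data.frame(
    code = d$code,
    width_m = haversine_m(midlat, d$west, midlat, d$east),
    height_m = haversine_m(d$south, d$west, d$north, d$west),
    stringsAsFactors = FALSE
  )
}

#' Great-circle distance in meters
#'
#' Haversine distance on a sphere of radius 6,371,000 m (mean Earth
#' radius). Vectorized with the usual recycling.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees.
#' @return Numeric vector of distances in meters.
#' @export
haversine_m <- function(lat1, lon1, lat2, lon2) {
  n <- max(length(lat1), length(lon1), length(lat2), length(lon2))
  if (n == 0L) return(numeric(0))
  lat1 <- rep_len(lat1, n); lon1 <- rep_len(lon1, n)
  lat2 <- rep_len(lat2, n); lon2 <- rep_len(lon2, n)
  if (any(!is.finite(c(lat1, lon1, lat2, lon2)))) {
    stop("non-finite coordinates", call. = FALSE)
  }
  if (any(abs(c(lat1, lat2)) > 90)) {
    stop("latitude out of range [-90, 90]", call. = FALSE)
  }
  k <- pi / 180
  a <- sin((lat2 - lat1) * k / 2)^2 +
    cos(lat1 * k) * cos(lat2 * k) * sin((lon2 - lon1) * k / 2)^2
  2 * 6371000 * asin(pmin(sqrt(a), 1))
}

.close_ring <- function(ring) {
  ring <- as.matrix(ring)
  if (!is.numeric(ring) || ncol(ring) != 2L) {
    stop("a ring must be a two-column (lon, lat) matrix", call. = FALSE)
  }
  if (nrow(unique(ring)) < 3L) {
    stop("degenerate ring: fewer than 3 distinct vertices", call. = FALSE)
  }
  if (any(ring[1L, ] != ring[nrow(ring), ])) {
    ring <- rbind(ring, ring[1L, ])
  }
  ring
}

.on_segment <- function(px, py, x1, y1, x2, y2, eps = 1e-12) {
  cross <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
  scale <- pmax(abs(x2 - x1), abs(y2 - y1), 1)
  abs(cross) <= eps * scale &
    px >= pmin(x1, x2) - eps & px <= pmax(x1, x2) + eps &
    py >= pmin(y1, y2) - eps & py <= pmax(y1, y2) + eps
}

#' Point-in-polygon test (even-odd rule)
#'
#' Ray-casting point-in-polygon membership for a polygon given as a list
#' of closed lon/lat rings: the first ring is the outer boundary,
#' subsequent rings are holes (even-odd rule, so a point inside a hole
#' is outside). Points exactly on any ring edge count as inside.
#'
#' @param lat,lon Numeric vectors of query points.
#' @param polygon A two-column (lon, lat) matrix for a single ring, or a
#'   list of such matrices (outer ring first, then holes). Rings are
#'   auto-closed if the first vertex is not repeated.
#' @return Logical vector, one per query point.
#' @export
point_in_polygon <- function(lat, lon, polygon) {
  if (is.matrix(polygon) || is.data.frame(polygon)) polygon <- list(polygon)
  rings <- lapply(polygon, .close_ring)
  n <- max(length(lat), length(lon))
  lat <- rep_len(lat, n); lon <- rep_len(lon, n)
  inside <- rep(FALSE, n)
  boundary <- rep(FALSE, n)
  for (ring in rings) {
    xs <- ring[, 1L]; ys <- ring[, 2L]
    for (i in seq_len(nrow(ring) - 1L)) {
      x1 <- xs[i]; y1 <- ys[i]; x2 <- xs[i + 1L]; y2 <- ys[i + 1L]
      boundary <- boundary | .on_segment(lon, lat, x1, y1, x2, y2)
      crosses <- ((y1 > lat) != (y2 > lat)) &
        (lon < (x2 - x1) * (lat - y1) / (y2 - y1) + x1)
      inside <- xor(inside, crosses)
    }
  }
  inside | boundary
}
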