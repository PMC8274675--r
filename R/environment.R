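# Environment characteristics of geohash cells from POI layers.

#' Default POI category-group mapping
#'
#' Maps each POI category to a broad group used for composites and for
#' visit-percentage indicators: fast food/takeaway, restaurants and
#' supermarkets/grocery stores form the `food` group; athletics/sports
#' facilities, indoor recreation facilities and public parks form the
#' `sports` group; anything else is `other`. Override by supplying your
#' own data.frame (columns `category`, `group`) or a YAML/JSON file via
#' [read_category_map()].
#'
#' @return A data.frame with columns `category`, `group`.
#' @export
default_category_map <- function() {
  data.frame(
    category = c("fast_food", "restaurant", "supermarket",
                 "sports_facility", "indoor_recreation", "public_park",
                 "other"),
    group = c("food", "food", "food",
              "sports", "sports", "sports",
              "other"),
    stringsAsFactors = FALSE
  )
}

.check_categories <- function(pois, category_map) {
  unknown <- setdiff(unique(as.character(pois$category)),
                     category_map$category)
  if (length(unknown)) {
    stop("POI categories absent from the category-group map: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Count POIs of a category inside geohash cells
#'
#' A POI belongs to the unique cell its coordinates encode to at the
#' cell's precision, so a point on a shared cell edge is counted in
#' exactly one cell.
#'
#' @param pois POI data.frame (`id`, `category`, `lat`, `lon`).
#' @param cells Character vector of geohash codes (must share one
#'   precision).
#' @param category POI category to count.
#' @param category_map Category-group mapping defining the known
#'   categories.
#' @return A data.frame `cell`, `characteristic`, `value` with
#'   `characteristic = "count_<category>"`.
#' @export
count_pois_in_cell <- function(pois, cells, category,
                               category_map = default_category_map()) {
  .gh_validate_codes(cells)
  if (length(unique(nchar(cells))) > 1L) {
    stop("cells must share one precision", call. = FALSE)
  }
  if (!category %in% pois$category && !category %in% category_map$category) {
    # a category neither in the layer nor in the map is a config error
    stop("unknown POI category: ", category, call. = FALSE)
  }
  p <- pois[pois$category == category, , drop = FALSE]
  counts <- integer(length(cells))
  if (nrow(p) > 0L && length(cells) > 0L) {
    code <- geohash_encode(p$lat, p$lon, nchar(cells[1L]))
    tab <- table(code)
    hit <- match(cells, names(tab))
    counts <- ifelse(is.na(hit), 0L, as.integer(tab[hit]))
  }
  data.frame(cell = cells,
             characteristic = paste0("count_", category),
             value = counts, stringsAsFactors = FALSE)
}

#' Grid-based radius density of a POI category in a cell
#'
#' Lays a point lattice of `grid_spacing_m` pitch over the cell's
#' bounding box (anchored at the southwest corner, points outside the
#' box excluded), counts for each lattice point the POIs of the
#' category within `radius_m` great-circle distance - POIs outside the
#' cell but within the radius do count - and returns the mean count
#' over lattice points.
#'
#' @param pois POI data.frame.
#' @param cell A single geohash code.
#' @param category POI category.
#' @param grid_spacing_m Lattice pitch, meters (default 30).
#' @param radius_m Counting radius, meters (default 100).
#' @return A data.frame `cell`, `characteristic`
#'   (`density<radius>_<category>`), `value`.
#' @export
grid_radius_density <- function(pois, cell, category,
                                grid_spacing_m = 30, radius_m = 100) {
  if (length(cell) != 1L) stop("one cell at a time", call. = FALSE)
  if (grid_spacing_m <= 0) stop("grid_spacing_m must be > 0", call. = FALSE)
  box <- geohash_decode(cell)
  midlat <- (box$south + box$north) / 2
  m_per_deg_lat <- 111320
  m_per_deg_lon <- 111320 * cos(midlat * pi / 180)
  if (m_per_deg_lon <= 0) stop("degenerate cell at the pole", call. = FALSE)
  lat_step <- grid_spacing_m / m_per_deg_lat
  lon_step <- grid_spacing_m / m_per_deg_lon
  lats <- seq(box$south, box$north, by = lat_step)
  lons <- seq(box$west, box$east, by = lon_step)
  grid <- expand.grid(lat = lats, lon = lons)
  p <- pois[pois$category == category, , drop = FALSE]
  value <- 0
  if (nrow(p) > 0L) {
    counts <- vapply(seq_len(nrow(grid)), function(i) {
      sum(haversine_m(grid$lat[i], grid$lon[i], p$lat, p$lon) <= radius_m)
    }, numeric(1))
    value <- mean(counts)
  }
  data.frame(cell = cell,
             characteristic = paste0("density", radius_m, "_", category),
             value = value, stringsAsFactors = FALSE)
}

#' Food / Sports composite availability
#'
#' Sums, per cell, the per-category counts whose category maps to the
#' requested group - the summation of all environmental characteristics
#' reflecting the availability of food places (or sports-related
#' facilities).
#'
#' @param env Long environment table with `count_<category>` rows.
#' @param group `"food"` or `"sports"` (any group in the map works).
#' @param category_map Category-group mapping.
#' @return A data.frame `cell`, `characteristic`
#'   (`composite_<group>`), `value`.
#' @export
composite_group <- function(env, group,
                            category_map = default_category_map()) {
  cats <- category_map$category[category_map$group == group]
  rows <- env[env$characteristic %in% paste0("count_", cats), ,
              drop = FALSE]
  cells <- unique(env$cell)
  value <- numeric(length(cells))
  if (nrow(rows) > 0L) {
    s <- tapply(rows$value, rows$cell, sum)
    hit <- match(cells, names(s))
    value <- ifelse(is.na(hit), 0, as.vector(s)[hit])
  }
  data.frame(cell = cells,
             characteristic = paste0("composite_", group),
             value = value, stringsAsFactors = FALSE)
}

#' Compute the full environment table for a set of cells
#'
#' Per-category POI counts for every category in the map that occurs in
#' the layer, optional grid-based radius densities for selected
#' categories, and the Food and Sports composites.
#'
#' @param pois POI data.frame.
#' @param cells Character vector of geohash codes at one precision.
#' @param category_map Category-group mapping.
#' @param density_categories Categories for which the 30-m-grid /
#'   100-m-radius density is also computed (default `"restaurant"`;
#'   use `character(0)` to skip the comparatively expensive lattice
#'   computation).
#' @param grid_spacing_m,radius_m Lattice parameters, meters.
#' @return A long data.frame `cell`, `characteristic`, `value`.
#' @export
compute_environment <- function(pois, cells,
                                category_map = default_category_map(),
                                density_categories = "restaurant",
                                grid_spacing_m = 30, radius_m = 100) {
  .check_categories(pois, category_map)
  cats <- intersect(category_map$category, unique(pois$category))
  cats <- union(cats, category_map$category[category_map$group %in%
                                              c("food", "sports")])
  parts <- lapply(sort(cats), function(ct) {
    count_pois_in_cell(pois, cells, ct, category_map)
  })
  env <- do.call(rbind, parts)
  for (ct in density_categories) {
    dens <- do.call(rbind, lapply(cells, function(cl) {
      grid_radius_density(pois, cl, ct, grid_spacing_m, radius_m)
    }))
    env <- rbind(env, dens)
  }
  env <- rbind(env,
               composite_group(env, "food", category_map),
               composite_group(env, "sports", category_map))
  rownames(env) <- NULL
  env
}
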