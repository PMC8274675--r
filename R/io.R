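# Readers and writers for the pipeline's file formats: trajectory CSV,
# POI CSV/GeoJSON, schools CSV, municipality GeoJSON, category-map
# YAML/JSON, tabular CSV/JSON outputs.

#' Read a POI layer (CSV or GeoJSON points)
#'
#' CSV needs columns `id,category,lat,lon`; GeoJSON must be a
#' FeatureCollection of Point features with a `category` property (an
#' `id` property is optional).
#'
#' @param path Path to the file; format chosen by extension
#'   (`.geojson` / `.json` vs anything else as CSV).
#' @return POI data.frame: `id`, `category`, `lat`, `lon`.
#' @export
read_pois <- function(path) {
  if (!file.exists(path)) stop("POI file not found: ", path, call. = FALSE)
  if (grepl("\\.(geojson|json)$", path, ignore.case = TRUE)) {
    gj <- jsonlite::read_json(path)
    feats <- gj$features
    out <- data.frame(
      id = vapply(seq_along(feats), function(i) {
        id <- feats[[i]]$properties$id
        if (is.null(id)) paste0("poi", i) else as.character(id)
      }, character(1)),
      category = vapply(feats, function(f) {
        as.character(f$properties$category)
      }, character(1)),
      lat = vapply(feats, function(f) {
        as.numeric(f$geometry$coordinates[[2L]])
      }, numeric(1)),
      lon = vapply(feats, function(f) {
        as.numeric(f$geometry$coordinates[[1L]])
      }, numeric(1)),
      stringsAsFactors = FALSE
    )
  } else {
    out <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("id", "category", "lat", "lon")
    if (!all(need %in% names(out))) {
      stop("POI CSV must have columns: ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    out <- out[need]
  }
  .check_latlon(out$lat, out$lon)
  out
}

#' Read a schools CSV
#'
#' Columns `id,lat,lon` and optionally `city`.
#'
#' @param path Path to the CSV.
#' @return School data.frame.
#' @export
read_schools <- function(path) {
  if (!file.exists(path)) stop("school file not found: ", path, call. = FALSE)
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "lat", "lon")
  if (!all(need %in% names(out))) {
    stop("school CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  .check_latlon(out$lat, out$lon)
  out
}

#' Read municipality boundaries from GeoJSON
#'
#' Accepts a FeatureCollection of Polygon or MultiPolygon features with
#' a `name` property. Rings are kept in GeoJSON (lon, lat) vertex
#' order; within each polygon the first ring is the outer boundary and
#' the rest are holes.
#'
#' @param path Path to the GeoJSON file.
#' @return A list of municipalities, each `list(name, rings)` with
#'   `rings` a list of closed two-column (lon, lat) matrices.
#' @export
read_municipalities <- function(path) {
  if (!file.exists(path)) {
    stop("municipality file not found: ", path, call. = FALSE)
  }
  gj <- jsonlite::read_json(path)
  ring_mat <- function(ring) {
    do.call(rbind, lapply(ring, function(pt) {
      c(as.numeric(pt[[1L]]), as.numeric(pt[[2L]]))
    }))
  }
  lapply(gj$features, function(f) {
    geom <- f$geometry
    rings <- switch(
      geom$type,
      Polygon = lapply(geom$coordinates, ring_mat),
      MultiPolygon = unlist(lapply(geom$coordinates, function(poly) {
        lapply(poly, ring_mat)
      }), recursive = FALSE),
      stop("unsupported geometry type: ", geom$type, call. = FALSE)
    )
    list(name = as.character(f$properties$name), rings = rings)
  })
}

#' Write municipalities to GeoJSON
#'
#' @param municipalities Municipality list (see
#'   [read_municipalities()]).
#' @param path Output path.
#' @export
write_municipalities <- function(municipalities, path) {
  feats <- lapply(municipalities, function(m) {
    coords <- lapply(m$rings, function(r) {
      lapply(seq_len(nrow(r)), function(i) c(r[i, 1L], r[i, 2L]))
    })
    list(type = "Feature",
         properties = list(name = m$name),
         geometry = list(type = "Polygon", coordinates = coords))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a category-group mapping from YAML or JSON
#'
#' The file maps categories to groups either flat
#' (`fast_food: food`) or grouped
#' (`food: [fast_food, restaurant]`).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A data.frame `category`, `group`.
#' @export
read_category_map <- function(path) {
  if (!file.exists(path)) {
    stop("category map not found: ", path, call. = FALSE)
  }
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (all(vapply(raw, length, 1L) == 1L)) {
    out <- data.frame(category = names(raw),
                      group = unlist(raw, use.names = FALSE),
                      stringsAsFactors = FALSE)
  } else {
    out <- do.call(rbind, lapply(names(raw), function(g) {
      data.frame(category = unlist(raw[[g]], use.names = FALSE),
                 group = g, stringsAsFactors = FALSE)
    }))
  }
  if (anyDuplicated(out$category)) {
    stop("category mapped to more than one group", call. = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Write a table as CSV and JSON
#'
#' The JSON mirror (row-wise records) matches the dashboard-style data
#' export so downstream consumers can pick either format.
#'
#' @param x Data.frame.
#' @param stem Output path without extension; writes `<stem>.csv` and
#'   `<stem>.json`.
#' @return The two paths, invisibly.
#' @export
write_table <- function(x, stem) {
  csv <- paste0(stem, ".csv")
  json <- paste0(stem, ".json")
  utils::write.csv(x, csv, row.names = FALSE)
  jsonlite::write_json(x, json, dataframe = "rows", digits = NA, na = "null")
  invisible(c(csv, json))
}

#' Write a fix table as trajectory CSV
#'
#' @param fixes Fix data.frame.
#' @param path Output path.
#' @export
write_fixes <- function(fixes, path) {
  out <- data.frame(
    child_id = fixes$child_id,
    timestamp = format(fixes$t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    lat = fixes$lat, lon = fixes$lon, steps = fixes$steps,
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
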