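# Minimal GeoJSON readers/writers for the package's planar layers.
#
# The files are standard GeoJSON FeatureCollections except that
# coordinates are planar metres in the analysis CRS (recorded in the
# collection's "crs_id" member) rather than longitude/latitude; all the
# package's thresholds are metric, so no geographic round trip is needed.

#' Write a point layer to GeoJSON
#'
#' @param points Data frame with `x`, `y` and property columns.
#' @param path Output file path.
#' @param crs_id CRS label stored on the collection.
#' @return `path`, invisibly.
#' @export
write_geojson_points <- function(points, path, crs_id = "local-metric") {
  props <- setdiff(names(points), c("x", "y"))
  features <- lapply(seq_len(nrow(points)), function(i) {
    list(
      type = "Feature",
      geometry = list(type = "Point",
                      coordinates = c(points$x[i], points$y[i])),
      properties = as.list(points[i, props, drop = FALSE])
    )
  })
  obj <- list(type = "FeatureCollection", crs_id = crs_id,
              features = features)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Read a point layer from GeoJSON
#'
#' @param path File written by [write_geojson_points()] (or any point
#'   FeatureCollection with scalar properties).
#' @return A tibble with `x`, `y` and the property columns.
#' @export
read_geojson_points <- function(path) {
  obj <- jsonlite::read_json(path)
  rows <- lapply(obj$features, function(f) {
    cc <- unlist(f$geometry$coordinates)
    props <- lapply(f$properties, function(p) if (is.null(p)) NA else p)
    tibble::as_tibble(c(list(x = cc[1], y = cc[2]), props))
  })
  dplyr::bind_rows(rows)
}

#' Write a polygon layer to GeoJSON
#'
#' @param rings List of rings (each a list with `x`, `y`).
#' @param properties Data frame with one row per ring.
#' @param path Output file path.
#' @param crs_id CRS label.
#' @return `path`, invisibly.
#' @export
write_geojson_polygons <- function(rings, properties, path,
                                   crs_id = "local-metric") {
  features <- lapply(seq_along(rings), function(i) {
    r <- rings[[i]]
    coords <- lapply(c(seq_along(r$x), 1L), function(k) c(r$x[k], r$y[k]))
    list(
      type = "Feature",
      geometry = list(type = "Polygon", coordinates = list(coords)),
      properties = as.list(properties[i, , drop = FALSE])
    )
  })
  obj <- list(type = "FeatureCollection", crs_id = crs_id,
              features = features)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Read a polygon layer from GeoJSON
#'
#' @param path File written by [write_geojson_polygons()].
#' @return A list with `rings` (list of `x`/`y` rings, closing vertex
#'   dropped) and `properties` (tibble).
#' @export
read_geojson_polygons <- function(path) {
  obj <- jsonlite::read_json(path)
  rings <- lapply(obj$features, function(f) {
    cc <- f$geometry$coordinates[[1]]
    x <- vapply(cc, function(p) as.numeric(p[[1]]), numeric(1))
    y <- vapply(cc, function(p) as.numeric(p[[2]]), numeric(1))
    n <- length(x)
    if (n > 1 && x[1] == x[n] && y[1] == y[n]) {
      x <- x[-n]; y <- y[-n]
    }
    list(x = x, y = y)
  })
  props <- dplyr::bind_rows(lapply(obj$features, function(f) {
    tibble::as_tibble(lapply(f$properties,
                             function(p) if (is.null(p)) NA else p))
  }))
  list(rings = rings, properties = props)
}

#' Export a full analysis run
#'
#' Writes the per-point indicator table (CSV), the hexagon summary
#' (GeoJSON, carrying walkability and open-space access for mapping), the
#' city summary row (CSV) and a JSON manifest (configuration echo) so a run
#' can be reproduced byte-for-byte.
#'
#' @param run A list as returned by [analyse_city()].
#' @param dir Output directory (created if needed).
#' @param manifest Named list echoed into `manifest.json` (seeds, config).
#' @return The directory path, invisibly.
#' @export
export_outputs <- function(run, dir, manifest = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(run$points, file.path(dir, "point_indicators.csv"),
                   row.names = FALSE)
  hx <- run$hexes
  utils::write.csv(hx, file.path(dir, "hex_summary.csv"), row.names = FALSE)
  if (all(c("cx", "cy") %in% names(hx))) {
    geom_cols <- setdiff(names(hx), character(0))
    pts <- hx
    pts$x <- pts$cx
    pts$y <- pts$cy
    write_geojson_points(pts[, c("x", "y", setdiff(geom_cols,
                                                   c("cx", "cy")))],
                         file.path(dir, "hex_summary.geojson"))
  }
  utils::write.csv(run$city, file.path(dir, "city_summary.csv"),
                   row.names = FALSE)
  manifest$written_utc <- format(Sys.time(), tz = "UTC")
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
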