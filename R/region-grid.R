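# Study-region definition and the two analysis lattices: the 250 m square
# population grid and the 250 m hexagonal neighbourhood layer.
#
# Both lattices are deterministic functions of the region's bounding box:
# the square grid is anchored at the bounding-box south-west corner, and the
# hexagon layer at the same origin. This anchoring is a package convention
# (documented, so runs are reproducible) rather than a property of the data.

#' Construct a study-region boundary
#'
#' @param polygon A data frame or list with numeric `x` and `y` vertex
#'   coordinates (metres, planar CRS), first vertex not repeated.
#' @param name Region name.
#' @param crs_id Free-text label of the planar CRS the coordinates are in.
#' @return A `region_boundary` object.
#' @export
region_boundary <- function(polygon, name = "region", crs_id = "local-metric") {
  x <- as.numeric(polygon$x)
  y <- as.numeric(polygon$y)
  if (length(x) < 3 || length(x) != length(y) || anyNA(x) || anyNA(y)) {
    stop("region polygon needs >= 3 finite vertices", call. = FALSE)
  }
  # drop a repeated closing vertex if present
  n <- length(x)
  if (x[1] == x[n] && y[1] == y[n]) {
    x <- x[-n]; y <- y[-n]
  }
  area <- polygon_area(x, y)
  if (area <= 0) stop("region polygon has zero area", call. = FALSE)
  if (self_intersects(x, y)) {
    stop("region polygon is self-intersecting", call. = FALSE)
  }
  structure(
    list(x = x, y = y, name = name, crs_id = crs_id, area_m2 = area),
    class = "region_boundary"
  )
}

#' @export
print.region_boundary <- function(x, ...) {
  cat(sprintf(
    "<region_boundary> %s: %d vertices, %.3f km^2 [%s]\n",
    x$name, length(x$x), x$area_m2 / 1e6, x$crs_id
  ))
  invisible(x)
}

# naive O(n^2) proper-crossing check; regions are small polygons
self_intersects <- function(x, y) {
  n <- length(x)
  nxt <- c(seq(2, n), 1L)
  seg_cross <- function(ax, ay, bx, by, cx, cy, dx, dy) {
    d1 <- (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
    d2 <- (bx - ax) * (dy - ay) - (by - ay) * (dx - ax)
    d3 <- (dx - cx) * (ay - cy) - (dy - cy) * (ax - cx)
    d4 <- (dx - cx) * (by - cy) - (dy - cy) * (bx - cx)
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  for (i in seq_len(n - 2L)) {
    for (j in seq(i + 2L, n)) {
      if (i == 1L && j == n) next  # adjacent through the wrap
      if (seg_cross(x[i], y[i], x[nxt[i]], y[nxt[i]],
                    x[j], y[j], x[nxt[j]], y[nxt[j]])) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Intersect an administrative boundary with an urban-extent polygon
#'
#' The study region is the intersection of a city administrative boundary
#' with an urbanised-extent polygon (for example an urban-centres layer),
#' so analysis is restricted to the contiguous urbanised part of the
#' municipality. The urban-extent polygon must be convex (rectangular or
#' hexagonal extents in practice); the administrative boundary may be any
#' simple polygon.
#'
#' @param admin A `region_boundary` (or coercible polygon) for the
#'   administrative boundary.
#' @param urban_extent A `region_boundary` (or coercible polygon), convex.
#' @param name Name for the resulting region.
#' @return A `region_boundary` for the intersection.
#' @export
build_study_region <- function(admin, urban_extent, name = NULL) {
  admin <- as_region(admin)
  urban_extent <- as_region(urban_extent)
  if (!identical(admin$crs_id, urban_extent$crs_id)) {
    stop("admin and urban_extent are in different CRSs: project first",
         call. = FALSE)
  }
  clipped <- clip_polygon(list(x = admin$x, y = admin$y),
                          list(x = urban_extent$x, y = urban_extent$y))
  if (length(clipped$x) < 3 || polygon_area(clipped$x, clipped$y) <= 1e-9) {
    stop("administrative boundary and urban extent do not overlap",
         call. = FALSE)
  }
  region_boundary(clipped,
                  name = name %||% admin$name,
                  crs_id = admin$crs_id)
}

as_region <- function(p, name = "region", crs_id = "local-metric") {
  if (inherits(p, "region_boundary")) p else region_boundary(p, name, crs_id)
}

#' Build the square population grid over a study region
#'
#' Tiles the region with axis-aligned square cells (250 m by default),
#' anchored at the south-west corner of the region's bounding box, and keeps
#' every cell whose square intersects the region polygon with positive area.
#' Populations start at 0 and are attached with [attach_population()] or by
#' the synthetic-city generator.
#'
#' @param region A `region_boundary`.
#' @param cell_size Cell side length in metres (default 250).
#' @return A tibble with `cell_id`, `col`, `row`, `xmin`, `ymin`, `xmax`,
#'   `ymax`, `population`, `area_km2`.
#' @export
build_square_grid <- function(region, cell_size = 250) {
  stopifnot(cell_size > 0)
  region <- as_region(region)
  x0 <- min(region$x); y0 <- min(region$y)
  nx <- ceiling((max(region$x) - x0) / cell_size - 1e-9)
  ny <- ceiling((max(region$y) - y0) / cell_size - 1e-9)
  cells <- tidyr::expand_grid(row = seq_len(ny) - 1L, col = seq_len(nx) - 1L)
  cells$xmin <- x0 + cells$col * cell_size
  cells$ymin <- y0 + cells$row * cell_size
  cells$xmax <- cells$xmin + cell_size
  cells$ymax <- cells$ymin + cell_size
  keep <- vapply(seq_len(nrow(cells)), function(i) {
    clipped <- clip_polygon(
      list(x = region$x, y = region$y),
      rect_ring(cells$xmin[i], cells$ymin[i], cells$xmax[i], cells$ymax[i])
    )
    length(clipped$x) >= 3 && polygon_area(clipped$x, clipped$y) > 1e-6
  }, logical(1))
  cells <- cells[keep, , drop = FALSE]
  tibble::tibble(
    cell_id = seq_len(nrow(cells)),
    col = cells$col, row = cells$row,
    xmin = cells$xmin, ymin = cells$ymin,
    xmax = cells$xmax, ymax = cells$ymax,
    population = 0,
    area_km2 = (cell_size / 1000)^2
  )
}

#' Attach population counts to grid cells
#'
#' @param grid A grid tibble from [build_square_grid()].
#' @param populations A data frame with `cell_id` and `population`.
#' @return The grid with its `population` column replaced; cells absent from
#'   `populations` keep 0. Total population is conserved.
#' @export
attach_population <- function(grid, populations) {
  stopifnot(all(c("cell_id", "population") %in% names(populations)))
  if (any(populations$population < 0)) {
    stop("cell populations must be nonnegative", call. = FALSE)
  }
  unknown <- setdiff(populations$cell_id, grid$cell_id)
  if (length(unknown)) {
    stop("population rows reference unknown cell_ids: ",
         paste(utils::head(unknown), collapse = ", "), call. = FALSE)
  }
  idx <- match(grid$cell_id, populations$cell_id)
  grid$population <- ifelse(is.na(idx), 0, populations$population[idx])
  grid
}

#' Build the hexagonal neighbourhood layer over a study region
#'
#' Flat-topped hexagons with flat-to-flat width 250 m by default, so each
#' hexagon has area (sqrt(3)/2) * width^2 (about 5.4 ha), comparable to a
#' 250 m grid cell. The layer is anchored at the region bounding-box
#' south-west corner and keeps hexagons that intersect the region.
#'
#' @param region A `region_boundary`.
#' @param width Flat-to-flat hexagon width in metres (default 250).
#' @return A tibble with `hex_id`, `cx`, `cy` (centroid) and list-columns
#'   `ring_x`, `ring_y` holding the six vertex coordinates.
#' @export
build_hex_grid <- function(region, width = 250) {
  stopifnot(width > 0)
  region <- as_region(region)
  r <- width / sqrt(3)              # circumradius (corner distance)
  x0 <- min(region$x); y0 <- min(region$y)
  x1 <- max(region$x); y1 <- max(region$y)
  ncol_ <- ceiling((x1 - x0) / (1.5 * r)) + 2L
  nrow_ <- ceiling((y1 - y0) / width) + 2L
  ang <- pi / 3 * (0:5)              # vertices at 0, 60, ..., 300 degrees
  out <- list()
  hex_id <- 0L
  for (col in seq(-1L, ncol_)) {
    cx <- x0 + 1.5 * r * col
    yoff <- if (col %% 2 == 0) 0 else width / 2
    for (row in seq(-1L, nrow_)) {
      cy <- y0 + width * row + yoff
      vx <- cx + r * cos(ang)
      vy <- cy + r * sin(ang)
      clipped <- clip_polygon(list(x = region$x, y = region$y),
                              list(x = vx, y = vy))
      if (length(clipped$x) >= 3 &&
          polygon_area(clipped$x, clipped$y) > 1e-6) {
        hex_id <- hex_id + 1L
        out[[hex_id]] <- tibble::tibble(
          hex_id = hex_id, cx = cx, cy = cy,
          ring_x = list(vx), ring_y = list(vy)
        )
      }
    }
  }
  if (!length(out)) stop("no hexagons intersect the region", call. = FALSE)
  dplyr::bind_rows(out)
}

#' Assign points to grid cells
#'
#' @param x,y Point coordinates (metres).
#' @param grid A grid tibble from [build_square_grid()].
#' @return Integer `cell_id` per point (`NA` when the point falls outside
#'   every retained cell). Points on shared cell boundaries go to the cell
#'   with the larger column/row index (half-open `[min, max)` convention).
#' @export
assign_cell <- function(x, y, grid) {
  size <- grid$xmax[1] - grid$xmin[1]
  # lattice origin is constant across cells: xmin = x0 + col * size
  x0 <- grid$xmin[1] - grid$col[1] * size
  y0 <- grid$ymin[1] - grid$row[1] * size
  col <- floor((x - x0) / size)
  row <- floor((y - y0) / size)
  grid$cell_id[match(paste(col, row), paste(grid$col, grid$row))]
}

#' Assign points to hexagons
#'
#' A hexagonal tiling is the Voronoi diagram of its centroids, so each point
#' belongs to the hexagon with the nearest centroid; boundary ties go to the
#' smallest `hex_id`.
#'
#' @param x,y Point coordinates (metres).
#' @param hexes A hex tibble from [build_hex_grid()].
#' @return Integer `hex_id` per point.
#' @export
assign_hex <- function(x, y, hexes) {
  n <- length(x)
  out <- integer(n)
  for (i in seq_len(n)) {
    d2 <- (hexes$cx - x[i])^2 + (hexes$cy - y[i])^2
    out[i] <- hexes$hex_id[which.min(d2)]   # which.min: first = lowest id
  }
  out
}

#' Grid-cell polygon rings
#'
#' @param grid A grid tibble.
#' @return List of rings (`x`, `y`) per cell, for export.
#' @keywords internal
grid_rings <- function(grid) {
  lapply(seq_len(nrow(grid)), function(i) {
    rect_ring(grid$xmin[i], grid$ymin[i], grid$xmax[i], grid$ymax[i])
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
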