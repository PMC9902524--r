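# Residential sample points at regular intervals along the street network.
#
# Sample points stand in for the (unknown) spatial distribution of
# dwellings: every 30 m of walkable street carries one. Offsets are
# measured from the lower-node-id endpoint of each edge so that the point
# set does not depend on edge direction in the input file.

#' Generate sample points along the network
#'
#' Per edge of length `L`: points at offsets `interval, 2*interval, ...,
#' k*interval` with `k = floor((L - 1 mm) / interval)` (the millimetre
#' epsilon keeps a point off the far node when `L` is an exact multiple).
#' Edges too short to receive any such point get a single midpoint point,
#' so every edge carries at least one sample point.
#'
#' When a populated `grid` is supplied, points falling in cells with zero
#' population (or outside the grid) are dropped — sample points proxy
#' residential locations, so unpopulated areas carry none.
#'
#' @param net A `street_network`.
#' @param interval Spacing in metres (default 30).
#' @param grid Optional population grid ([build_square_grid()]); when given,
#'   points in zero-population cells are dropped and `cell_id` is attached.
#' @param hexes Optional hex layer ([build_hex_grid()]); when given,
#'   `hex_id` is attached.
#' @return A tibble with `point_id`, `edge_id`, `offset_m`, `x`, `y` and,
#'   when the lattices are supplied, `cell_id` and `hex_id`.
#' @export
generate_sample_points <- function(net, interval = 30, grid = NULL,
                                   hexes = NULL) {
  stopifnot(inherits(net, "street_network"), interval > 0)
  eps <- 1e-3
  edges <- net$edges[order(net$edges$edge_id), ]
  offs <- lapply(seq_len(nrow(edges)), function(i) {
    L <- edges$length_m[i]
    k <- floor((L - eps) / interval)
    if (k < 1) L / 2 else interval * seq_len(k)
  })
  n_per <- lengths(offs)
  pts <- tibble::tibble(
    edge_id = rep(edges$edge_id, n_per),
    offset_m = unlist(offs)
  )
  xy <- edge_point(net, pts$edge_id, pts$offset_m)
  pts$x <- xy$x
  pts$y <- xy$y
  if (!is.null(grid)) {
    pts$cell_id <- assign_cell(pts$x, pts$y, grid)
    pop <- grid$population[match(pts$cell_id, grid$cell_id)]
    pts <- pts[!is.na(pts$cell_id) & pop > 0, , drop = FALSE]
  }
  if (!is.null(hexes)) {
    pts$hex_id <- assign_hex(pts$x, pts$y, hexes)
  }
  pts <- dplyr::arrange(pts, .data$edge_id, .data$offset_m)
  pts$point_id <- seq_len(nrow(pts))
  dplyr::relocate(pts, "point_id")
}
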