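# Destination access: snapping destinations onto the street network,
# deriving public-open-space entry points, nearest network distances and
# the 500 m binary access score.

DEST_CLASSES <- c("food_market", "convenience", "pt_stop_any",
                  "pt_stop_30min", "pt_stop_20min",
                  "pos_any_entry", "pos_large_entry")

#' Construct a destination layer
#'
#' @param points Tibble with `dest_id`, `x`, `y` and (after snapping)
#'   `edge_id`, `offset_m`, `snap_dist`.
#' @param class_label One of `r paste(DEST_CLASSES, collapse = ", ")`.
#' @return The tibble with class `destination_layer` and a `class_label`
#'   attribute.
#' @export
destination_layer <- function(points, class_label) {
  class_label <- match.arg(class_label, DEST_CLASSES)
  points <- tibble::as_tibble(points)
  attr(points, "class_label") <- class_label
  class(points) <- c("destination_layer", class(points))
  points
}

#' @export
print.destination_layer <- function(x, ...) {
  cat(sprintf("<destination_layer> %s: %d point(s)%s\n",
              attr(x, "class_label"), nrow(x),
              if ("edge_id" %in% names(x)) ", snapped" else ""))
  invisible(x)
}

layer_label <- function(layer) attr(layer, "class_label")

#' Snap destination points onto the street network
#'
#' Each point is projected onto its nearest edge (ties broken towards the
#' lower `edge_id`); points farther than `tolerance` from every edge are
#' dropped with a warning. Offsets are measured from the lower-node-id
#' endpoint; on edges whose stored length exceeds the straight-line node
#' distance the offset is scaled proportionally.
#'
#' @param net A `street_network`.
#' @param points Data frame with `x`, `y` and optionally `dest_id`.
#' @param class_label Destination class for the resulting layer.
#' @param tolerance Maximum snap distance in metres (default 500).
#' @return A snapped `destination_layer`.
#' @export
snap_to_network <- function(net, points, class_label, tolerance = 500) {
  stopifnot(inherits(net, "street_network"))
  points <- tibble::as_tibble(points)
  if (!"dest_id" %in% names(points)) points$dest_id <- seq_len(nrow(points))
  edges <- net$edges
  iu <- match(edges$u, net$nodes$node_id)
  iv <- match(edges$v, net$nodes$node_id)
  ax <- net$nodes$x[iu]; ay <- net$nodes$y[iu]
  bx <- net$nodes$x[iv]; by <- net$nodes$y[iv]
  n <- nrow(points)
  edge_id <- integer(n); offset_m <- numeric(n); snap_dist <- numeric(n)
  for (i in seq_len(n)) {
    pr <- project_point_segment(points$x[i], points$y[i], ax, ay, bx, by)
    best <- which(pr$dist <= min(pr$dist) + 1e-9)
    best <- best[which.min(edges$edge_id[best])]
    edge_id[i] <- edges$edge_id[best]
    offset_m[i] <- pr$t[best] * edges$length_m[best]
    snap_dist[i] <- pr$dist[best]
  }
  keep <- snap_dist <= tolerance
  if (!any(keep)) {
    stop("no destination could be snapped within the tolerance",
         call. = FALSE)
  }
  if (any(!keep)) {
    warning(sprintf("%d destination(s) farther than %g m from the network were dropped",
                    sum(!keep), tolerance))
  }
  destination_layer(
    tibble::tibble(
      dest_id = points$dest_id[keep],
      x = points$x[keep], y = points$y[keep],
      edge_id = edge_id[keep], offset_m = offset_m[keep],
      snap_dist = snap_dist[keep]
    ),
    class_label
  )
}

#' Public open space entry points
#'
#' Pedestrian access to an open space happens along its boundary, so entry
#' points are generated every `spacing` metres along each polygon's
#' perimeter (starting at its first vertex) and snapped to the network. Two
#' layers are returned: all entries (`pos_any_entry`) and entries of spaces
#' strictly larger than `large_threshold_ha` (`pos_large_entry`).
#'
#' @param pos Tibble of axis-aligned rectangles with `pos_id`, `xmin`,
#'   `ymin`, `xmax`, `ymax` (and optionally `area_ha`, otherwise computed).
#' @param net A `street_network`.
#' @param spacing Entry-point spacing along the boundary, metres
#'   (default 20).
#' @param large_threshold_ha Area class boundary in hectares (default 1.5;
#'   the large class is strictly greater).
#' @param tolerance Snap tolerance passed to [snap_to_network()].
#' @return Named list with `pos_any_entry` and `pos_large_entry` layers.
#' @export
pos_entry_points <- function(pos, net, spacing = 20,
                             large_threshold_ha = 1.5, tolerance = 500) {
  stopifnot(spacing > 0)
  pos <- tibble::as_tibble(pos)
  if (!"area_ha" %in% names(pos)) {
    pos$area_ha <- (pos$xmax - pos$xmin) * (pos$ymax - pos$ymin) / 1e4
  }
  degenerate <- pos$area_ha <= 0
  if (any(degenerate)) {
    warning(sprintf("%d degenerate open-space polygon(s) skipped",
                    sum(degenerate)))
    pos <- pos[!degenerate, , drop = FALSE]
  }
  entries <- lapply(seq_len(nrow(pos)), function(i) {
    ring <- rect_ring(pos$xmin[i], pos$ymin[i], pos$xmax[i], pos$ymax[i])
    pts <- ring_points(ring, spacing)
    tibble::tibble(pos_id = pos$pos_id[i], x = pts$x, y = pts$y,
                   area_ha = pos$area_ha[i])
  })
  entries <- dplyr::bind_rows(entries)
  entries$dest_id <- seq_len(nrow(entries))
  any_layer <- snap_to_network(net, entries, "pos_any_entry", tolerance)
  any_layer$pos_id <- entries$pos_id[match(any_layer$dest_id,
                                           entries$dest_id)]
  any_layer$area_ha <- entries$area_ha[match(any_layer$dest_id,
                                             entries$dest_id)]
  large <- any_layer[any_layer$area_ha > large_threshold_ha, , drop = FALSE]
  large <- destination_layer(large, "pos_large_entry")
  list(pos_any_entry = any_layer, pos_large_entry = large)
}

# equally spaced points along a closed ring, starting at the first vertex
ring_points <- function(ring, spacing) {
  x <- c(ring$x, ring$x[1])
  y <- c(ring$y, ring$y[1])
  seg_len <- sqrt(diff(x)^2 + diff(y)^2)
  cum <- c(0, cumsum(seg_len))
  perim <- cum[length(cum)]
  n <- max(1L, floor(perim / spacing))
  s <- spacing * (seq_len(n) - 1L)
  seg <- findInterval(s, cum, rightmost.closed = TRUE)
  t <- (s - cum[seg]) / seg_len[seg]
  list(x = x[seg] + t * (x[seg + 1L] - x[seg]),
       y = y[seg] + t * (y[seg + 1L] - y[seg]))
}

#' Nearest network distance from a sample point to a destination layer
#'
#' Minimum network distance from the origin to any snapped destination.
#' Distances beyond `cap` are censored at the cap (binary access at any
#' sensible threshold is then 0); an empty layer yields a censored result
#' with a warning rather than an error, mirroring cities with no data for a
#' destination class.
#'
#' @param net A `street_network`.
#' @param origin One-row sample-point data frame (`edge_id`, `offset_m`).
#' @param layer A snapped `destination_layer`.
#' @param cap Search/censoring cap in metres (default 3200).
#' @param dmat Optional precomputed distance matrix.
#' @return A list with `distance_m` (censored at `cap`) and `censored`.
#' @export
nearest_distance <- function(net, origin, layer, cap = 3200, dmat = NULL) {
  if (!nrow(layer)) {
    warning("empty destination layer: distance censored at cap")
    return(list(distance_m = cap, censored = TRUE))
  }
  if (!"edge_id" %in% names(layer)) {
    stop("layer must be snapped first (see snap_to_network)", call. = FALSE)
  }
  dn <- origin_node_distances(net, origin$edge_id[1], origin$offset_m[1],
                              dmat)
  names(dn) <- as.character(net$nodes$node_id)
  ed <- net$edges[match(layer$edge_id, net$edges$edge_id), ]
  via_u <- dn[as.character(ed$u)] + layer$offset_m
  via_v <- dn[as.character(ed$v)] + (ed$length_m - layer$offset_m)
  d <- pmin(via_u, via_v)
  same <- layer$edge_id == origin$edge_id[1]
  if (any(same)) {
    d[same] <- pmin(d[same], abs(layer$offset_m[same] - origin$offset_m[1]))
  }
  dmin <- min(d)
  if (!is.finite(dmin) || dmin > cap) {
    list(distance_m = cap, censored = TRUE)
  } else {
    list(distance_m = dmin, censored = FALSE)
  }
}

#' Binary access score
#'
#' 1 when the access distance is within the threshold ("within" is
#' inclusive), 0 otherwise; censored distances score 0.
#'
#' @param distance_m Nonnegative distance(s) in metres.
#' @param threshold Access threshold in metres (default 500).
#' @param censored Logical, same length as `distance_m` (recycled).
#' @return Integer vector of 0/1.
#' @export
binary_access <- function(distance_m, threshold = 500, censored = FALSE) {
  if (any(distance_m < 0, na.rm = TRUE)) {
    stop("negative access distance", call. = FALSE)
  }
  as.integer(!censored & !is.na(distance_m) & distance_m <= threshold)
}
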