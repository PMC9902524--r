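# Pedestrian street network: data model, validation, component extraction
# and shortest-path services.
#
# The walking network is undirected (one-way restrictions do not apply to
# pedestrians). Edges are stored with endpoints normalised so that
# `u < v`; sample-point and destination offsets are measured from the
# lower-id endpoint, making all outputs independent of edge direction in
# the input file. Shortest paths are delegated to igraph.

#' Load and validate a street network
#'
#' @param nodes Data frame with `node_id`, `x`, `y` (metres, planar CRS).
#' @param edges Data frame with `edge_id`, `u`, `v` and optionally
#'   `length_m`. Missing lengths are derived from straight-line node
#'   geometry. A supplied `length_m` may exceed the straight-line distance
#'   (curved streets) but must not undercut it by more than 0.5 m.
#' @return A `street_network` object: list with tibbles `nodes` (including
#'   `degree`) and `edges`, plus the underlying igraph graph.
#' @export
load_network <- function(nodes, edges) {
  nodes <- tibble::as_tibble(nodes)
  edges <- tibble::as_tibble(edges)
  stopifnot(all(c("node_id", "x", "y") %in% names(nodes)),
            all(c("edge_id", "u", "v") %in% names(edges)))
  if (anyDuplicated(nodes$node_id)) {
    stop("duplicate node ids", call. = FALSE)
  }
  if (anyDuplicated(edges$edge_id)) {
    stop("duplicate edge ids", call. = FALSE)
  }
  if (!all(is.finite(nodes$x)) || !all(is.finite(nodes$y))) {
    stop("node coordinates must be finite", call. = FALSE)
  }
  dangling <- setdiff(c(edges$u, edges$v), nodes$node_id)
  if (length(dangling)) {
    stop("edge endpoints missing from node table: ",
         paste(utils::head(dangling), collapse = ", "), call. = FALSE)
  }
  if (any(edges$u == edges$v)) {
    stop("self-loop edges are not supported", call. = FALSE)
  }
  # normalise endpoint order so offsets are measured from the lower node id
  swap <- edges$u > edges$v
  tmp <- edges$u[swap]
  edges$u[swap] <- edges$v[swap]
  edges$v[swap] <- tmp
  iu <- match(edges$u, nodes$node_id)
  iv <- match(edges$v, nodes$node_id)
  straight <- sqrt((nodes$x[iu] - nodes$x[iv])^2 +
                   (nodes$y[iu] - nodes$y[iv])^2)
  if (!"length_m" %in% names(edges)) edges$length_m <- NA_real_
  edges$length_m <- ifelse(is.na(edges$length_m), straight, edges$length_m)
  if (any(edges$length_m <= 0)) {
    stop("edge lengths must be positive", call. = FALSE)
  }
  if (any(edges$length_m < straight - 0.5)) {
    stop("edge length below straight-line node distance", call. = FALSE)
  }
  edges <- edges[order(edges$edge_id), c("edge_id", "u", "v", "length_m")]
  nodes <- nodes[order(nodes$node_id), c("node_id", "x", "y")]
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(edges$u), to = as.character(edges$v),
               weight = edges$length_m, edge_id = edges$edge_id),
    directed = FALSE,
    vertices = data.frame(name = as.character(nodes$node_id))
  )
  nodes$degree <- as.integer(igraph::degree(g))
  structure(list(nodes = nodes, edges = edges, graph = g),
            class = "street_network")
}

#' @export
print.street_network <- function(x, ...) {
  cat(sprintf(
    "<street_network> %d nodes, %d edges, %.1f km, %d component(s)\n",
    nrow(x$nodes), nrow(x$edges), sum(x$edges$length_m) / 1000,
    igraph::count_components(x$graph)
  ))
  invisible(x)
}

#' Keep the largest connected component
#'
#' Reachability-based indicators are only well defined on a connected
#' network. Ties between equal-size components are broken in favour of the
#' component containing the smallest node id.
#'
#' @param net A `street_network`.
#' @return A `street_network` induced by the largest component.
#' @export
largest_component <- function(net) {
  stopifnot(inherits(net, "street_network"))
  if (nrow(net$nodes) == 0) stop("empty network", call. = FALSE)
  comp <- igraph::components(net$graph)
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1) {
    # tie-break: component whose minimum node id is smallest
    min_ids <- vapply(best, function(k) {
      min(as.integer(names(comp$membership)[comp$membership == k]))
    }, numeric(1))
    best <- best[which.min(min_ids)]
  } else {
    best <- best[1]
  }
  keep_ids <- as.integer(names(comp$membership)[comp$membership == best])
  nodes <- net$nodes[net$nodes$node_id %in% keep_ids, ]
  edges <- net$edges[net$edges$u %in% keep_ids & net$edges$v %in% keep_ids, ]
  load_network(nodes[, c("node_id", "x", "y")], edges)
}

#' All-pairs network distance matrix
#'
#' Node-to-node shortest-path distances (metres), used to vectorise the
#' per-sample-point computations. Row/column order follows `net$nodes`.
#'
#' @param net A `street_network`.
#' @return Numeric matrix with dimnames set to node ids.
#' @export
network_distance_matrix <- function(net) {
  d <- igraph::distances(net$graph, weights = igraph::E(net$graph)$weight)
  d <- d[as.character(net$nodes$node_id), as.character(net$nodes$node_id)]
  d
}

# Distances from every node to the two endpoints of an origin's edge,
# combined through the origin's offset. Returns the vector of shortest
# distances origin -> node over all nodes (order = net$nodes). Exact
# because any path from a mid-edge origin leaves via one of its endpoints.
origin_node_distances <- function(net, edge_id, offset_m, dmat = NULL) {
  e <- net$edges[net$edges$edge_id == edge_id, ]
  if (nrow(e) != 1) stop("origin edge not in network", call. = FALSE)
  if (offset_m < 0 || offset_m > e$length_m + 1e-9) {
    stop("origin offset outside its edge", call. = FALSE)
  }
  if (is.null(dmat)) {
    d2 <- igraph::distances(net$graph,
                            v = as.character(c(e$u, e$v)),
                            weights = igraph::E(net$graph)$weight)
    du <- d2[1, as.character(net$nodes$node_id)]
    dv <- d2[2, as.character(net$nodes$node_id)]
  } else {
    du <- dmat[as.character(e$u), ]
    dv <- dmat[as.character(e$v), ]
  }
  unname(pmin(offset_m + du, (e$length_m - offset_m) + dv))
}

#' Network distances from a sample point to all nodes within a cutoff
#'
#' The origin sits mid-edge; it reaches the rest of the network through
#' either endpoint of its edge, whichever is shorter (loops included).
#'
#' @param net A `street_network`.
#' @param origin A one-row data frame with `edge_id` and `offset_m`
#'   (typically a row of [generate_sample_points()] output).
#' @param cutoff Maximum distance in metres; nodes farther than this are
#'   omitted. `Inf` returns all reachable nodes.
#' @param dmat Optional precomputed [network_distance_matrix()] for batch
#'   work.
#' @return A tibble with `node_id` and `distance_m`, sorted by node id.
#' @export
shortest_distances <- function(net, origin, cutoff = Inf, dmat = NULL) {
  d <- origin_node_distances(net, origin$edge_id[1], origin$offset_m[1], dmat)
  keep <- is.finite(d) & d <= cutoff
  tibble::tibble(node_id = net$nodes$node_id[keep], distance_m = d[keep])
}

# Interpolated coordinates at a given offset from the lower-id endpoint of
# an edge (straight-line edge geometry).
edge_point <- function(net, edge_id, offset_m) {
  e <- net$edges[match(edge_id, net$edges$edge_id), ]
  iu <- match(e$u, net$nodes$node_id)
  iv <- match(e$v, net$nodes$node_id)
  t <- offset_m / e$length_m
  list(x = net$nodes$x[iu] + t * (net$nodes$x[iv] - net$nodes$x[iu]),
       y = net$nodes$y[iu] + t * (net$nodes$y[iv] - net$nodes$y[iu]))
}
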