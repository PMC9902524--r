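# Independent brute-force oracles used to validate the fast implementations.
# These deliberately avoid igraph and the package's interval arithmetic:
# shortest paths come from plain Bellman-Ford relaxation over the edge
# list, reached length from dense per-metre labelling, cell membership
# from dense point sampling, and nearest distances from a per-destination
# scan.

# Bellman-Ford over an undirected edge list; returns named distance vector.
oracle_bf <- function(nodes, edges, src_id) {
  d <- stats::setNames(rep(Inf, nrow(nodes)), as.character(nodes$node_id))
  d[as.character(src_id)] <- 0
  repeat {
    changed <- FALSE
    for (i in seq_len(nrow(edges))) {
      u <- as.character(edges$u[i])
      v <- as.character(edges$v[i])
      w <- edges$length_m[i]
      if (d[[u]] + w < d[[v]] - 1e-9) { d[[v]] <- d[[u]] + w; changed <- TRUE }
      if (d[[v]] + w < d[[u]] - 1e-9) { d[[u]] <- d[[v]] + w; changed <- TRUE }
    }
    if (!changed) break
  }
  d
}

# Distances from a mid-edge origin to all nodes: insert a pseudo-node
# splitting the origin edge, then Bellman-Ford from it.
oracle_origin_distances <- function(net, edge_id, offset_m) {
  e <- net$edges[net$edges$edge_id == edge_id, ]
  pseudo <- max(net$nodes$node_id) + 1L
  nodes <- rbind(net$nodes[, "node_id", drop = FALSE],
                 data.frame(node_id = pseudo))
  edges <- net$edges[net$edges$edge_id != edge_id,
                     c("u", "v", "length_m")]
  edges <- rbind(edges,
                 data.frame(u = e$u, v = pseudo, length_m = offset_m),
                 data.frame(u = pseudo, v = e$v,
                            length_m = e$length_m - offset_m))
  edges <- edges[edges$length_m > 0, ]
  d <- oracle_bf(nodes, edges, pseudo)
  d[as.character(net$nodes$node_id)]
}

# Reached street length by dense labelling: positions every `step` metres
# on every edge, labelled with their exact network distance from the
# origin, counted when within the cutoff.
oracle_reached_length <- function(net, origin, cutoff, step = 0.5) {
  d <- oracle_origin_distances(net, origin$edge_id[1], origin$offset_m[1])
  total <- 0
  for (i in seq_len(nrow(net$edges))) {
    e <- net$edges[i, ]
    t <- seq(step / 2, e$length_m - step / 2, by = step)
    dist_t <- pmin(d[[as.character(e$u)]] + t,
                   d[[as.character(e$v)]] + e$length_m - t)
    if (e$edge_id == origin$edge_id[1]) {
      dist_t <- pmin(dist_t, abs(t - origin$offset_m[1]))
    }
    total <- total + step * sum(dist_t <= cutoff)
  }
  total
}

# Cell membership by dense point sampling along every reached sub-segment,
# half-open cell convention; a cell counts when at least two samples fall
# in it (positive-length overlap).
oracle_catchment_cells <- function(net, reached, grid, step = 0.05) {
  size <- grid$xmax[1] - grid$xmin[1]
  x0 <- grid$xmin[1] - grid$col[1] * size
  y0 <- grid$ymin[1] - grid$row[1] * size
  counts <- list()
  for (i in seq_len(nrow(reached))) {
    offs <- seq(reached$from_m[i], reached$to_m[i], by = step)
    p <- walkshed:::edge_point(net, rep(reached$edge_id[i], length(offs)),
                               offs)
    key <- paste(floor((p$x - x0) / size), floor((p$y - y0) / size))
    tab <- table(key)
    for (k in names(tab)) {
      counts[[k]] <- (counts[[k]] %||% 0) + tab[[k]]
    }
  }
  keys <- names(counts)[unlist(counts) >= 2]
  ids <- grid$cell_id[match(keys, paste(grid$col, grid$row))]
  sort(ids[!is.na(ids)])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Nearest destination by per-destination scan over Bellman-Ford distances.
oracle_nearest <- function(net, origin, layer, cap = 3200) {
  if (!nrow(layer)) return(cap)
  d <- oracle_origin_distances(net, origin$edge_id[1], origin$offset_m[1])
  best <- Inf
  for (j in seq_len(nrow(layer))) {
    e <- net$edges[net$edges$edge_id == layer$edge_id[j], ]
    dj <- min(d[[as.character(e$u)]] + layer$offset_m[j],
              d[[as.character(e$v)]] + e$length_m - layer$offset_m[j])
    if (layer$edge_id[j] == origin$edge_id[1]) {
      dj <- min(dj, abs(layer$offset_m[j] - origin$offset_m[1]))
    }
    best <- min(best, dj)
  }
  min(best, cap)
}
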