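test_that("load_network derives lengths and validates integrity", {
  nodes <- tibble::tibble(node_id = 1:2, x = c(0, 300), y = c(0, 400))
  edges <- tibble::tibble(edge_id = 1, u = 1, v = 2)
  net <- load_network(nodes, edges)
  expect_equal(net$edges$length_m, 500)

  expect_error(
    load_network(nodes, tibble::tibble(edge_id = c(1, 1), u = c(1, 1),
                                       v = c(2, 2))),
    "duplicate edge ids"
  )
  expect_error(
    load_network(nodes, tibble::tibble(edge_id = 1, u = 1, v = 3)),
    "missing from the node table|missing"
  )
  expect_error(
    load_network(nodes, tibble::tibble(edge_id = 1, u = 1, v = 2,
                                       length_m = -5)),
    "positive|below"
  )
})

test_that("network round-trips through GeoJSON/CSV layers", {
  net <- make_random_net(3, n = 15)
  dir <- withr::local_tempdir()
  write_geojson_points(net$nodes, file.path(dir, "nodes.geojson"))
  utils::write.csv(net$edges, file.path(dir, "edges.csv"),
                   row.names = FALSE)
  nodes2 <- read_geojson_points(file.path(dir, "nodes.geojson"))
  edges2 <- utils::read.csv(file.path(dir, "edges.csv"))
  net2 <- load_network(nodes2, edges2)
  expect_equal(nrow(net2$nodes), nrow(net$nodes))
  expect_equal(nrow(net2$edges), nrow(net$edges))
  expect_equal(net2$edges$length_m, net$edges$length_m)
})

test_that("largest_component keeps the biggest component with id tie-break", {
  nodes <- tibble::tibble(node_id = 1:7,
                          x = c(0, 1, 2, 3, 4, 10, 11) * 100, y = 0)
  edges <- tibble::tibble(edge_id = 1:5,
                          u = c(1, 2, 3, 4, 6), v = c(2, 3, 4, 5, 7))
  net <- load_network(nodes, edges)
  lc <- largest_component(net)
  expect_setequal(lc$nodes$node_id, 1:5)

  # equal-size components: the one containing the smallest node id wins
  nodes <- tibble::tibble(node_id = 1:6, x = c(0, 1, 2, 10, 11, 12) * 100,
                          y = 0)
  edges <- tibble::tibble(edge_id = 1:4, u = c(1, 2, 4, 5),
                          v = c(2, 3, 5, 6))
  lc <- largest_component(load_network(nodes, edges))
  expect_setequal(lc$nodes$node_id, 1:3)

  # connected network: identity
  p <- make_path_net(3)
  expect_equal(largest_component(p)$edges, p$edges)
})

test_that("sample points follow the offset rule", {
  nodes <- tibble::tibble(node_id = 1:2, x = c(0, 100), y = 0)
  net <- load_network(nodes, tibble::tibble(edge_id = 1, u = 1, v = 2))
  pts <- generate_sample_points(net, 30)
  expect_equal(pts$offset_m, c(30, 60, 90))

  nodes$x[2] <- 20
  net <- load_network(nodes, tibble::tibble(edge_id = 1, u = 1, v = 2))
  pts <- generate_sample_points(net, 30)
  expect_equal(pts$offset_m, 10)  # short edge: one midpoint point

  # exact multiple: no point lands on the far node, midpoint fallback
  nodes$x[2] <- 30
  net <- load_network(nodes, tibble::tibble(edge_id = 1, u = 1, v = 2))
  expect_equal(generate_sample_points(net, 30)$offset_m, 15)
})

test_that("a 5x5 lattice of 250 m edges yields 8 points per edge", {
  spec <- city_spec(seed = 1, extent_m = 1000, block_m = 250)
  net <- generate_street_network(spec)
  pts <- generate_sample_points(net, 30)
  expect_equal(nrow(net$edges), 40)
  expect_equal(nrow(pts), 40 * 8)
})

test_that("sample points are invariant to edge order and direction", {
  net <- make_random_net(5, n = 20)
  pts1 <- generate_sample_points(net, 30)
  shuffled <- withr::with_seed(1, net$edges[sample.int(nrow(net$edges)), ])
  flipped <- shuffled
  tmp <- flipped$u
  flipped$u <- flipped$v
  flipped$v <- tmp
  net2 <- load_network(net$nodes[, c("node_id", "x", "y")], flipped)
  pts2 <- generate_sample_points(net2, 30)
  key <- function(p) p[order(p$edge_id, p$offset_m),
                       c("edge_id", "offset_m", "x", "y")]
  expect_equal(key(pts1), key(pts2))
})

test_that("points in unpopulated cells are dropped when a grid is given", {
  net <- make_path_net(4, edge_len = 250)  # 1 km line
  region <- region_boundary(list(x = c(0, 1000, 1000, 0),
                                 y = c(-125, -125, 125, 125)))
  grid <- build_square_grid(region)
  grid$population <- ifelse(grid$xmin < 500, 5, 0)
  pts <- generate_sample_points(net, 30, grid = grid)
  expect_true(all(pts$x < 500))
  expect_true(all(grid$population[match(pts$cell_id, grid$cell_id)] > 0))
})

test_that("shortest distances match additivity and scaling properties", {
  net <- make_path_net(2, edge_len = 100)
  net$edges$length_m <- c(100, 200)
  net <- load_network(net$nodes[, c("node_id", "x", "y")],
                      net$edges[, c("edge_id", "u", "v", "length_m")])
  origin <- tibble::tibble(edge_id = 1, offset_m = 0)
  d <- shortest_distances(net, origin)
  expect_equal(d$distance_m[d$node_id == 3], 300)

  # cutoff 0 keeps at most the origin's own node
  d0 <- shortest_distances(net, origin, cutoff = 0)
  expect_true(all(d0$distance_m == 0))

  # doubling every edge length doubles all distances
  net2 <- net
  net2$edges$length_m <- net$edges$length_m * 2
  net2 <- load_network(net2$nodes[, c("node_id", "x", "y")],
                       net2$edges[, c("edge_id", "u", "v", "length_m")])
  d1 <- shortest_distances(net, origin)
  d2 <- shortest_distances(net2, origin)
  expect_equal(d2$distance_m, d1$distance_m * 2)
})

test_that("shortest distances agree with a Bellman-Ford oracle", {
  for (seed in c(21, 22)) {
    net <- make_random_net(seed, n = 50, k = 3)
    origins <- tibble::tibble(edge_id = net$edges$edge_id[c(1, 7)],
                              offset_m = net$edges$length_m[c(1, 7)] * 0.4)
    for (i in 1:2) {
      d <- shortest_distances(net, origins[i, ])
      ora <- oracle_origin_distances(net, origins$edge_id[i],
                                     origins$offset_m[i])
      expect_equal(d$distance_m,
                   unname(ora[as.character(d$node_id)]),
                   tolerance = 1e-9)
    }
  }
})

test_that("triangle inequality holds on network distances", {
  net <- make_random_net(31, n = 25)
  dm <- network_distance_matrix(net)
  n <- nrow(dm)
  withr::with_seed(1, idx <- matrix(sample.int(n, 60, replace = TRUE), 20))
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]; k <- idx[r, 3]
    expect_lte(dm[i, j], dm[i, k] + dm[k, j] + 1e-9)
  }
})
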