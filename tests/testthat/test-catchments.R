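test_that("reachable network trims partial edges at the cutoff", {
  net <- make_path_net(4, edge_len = 300)
  origin <- tibble::tibble(edge_id = 1, offset_m = 0)
  reached <- reachable_network(net, origin, cutoff = 1000)
  full <- reached[reached$edge_id <= 3, ]
  expect_equal(full$from_m, rep(0, 3))
  expect_equal(full$to_m, rep(300, 3))
  e4 <- reached[reached$edge_id == 4, ]
  expect_equal(e4$to_m - e4$from_m, 100)

  # cutoff beyond the network diameter reaches everything fully
  all_r <- reachable_network(net, origin, cutoff = 1e6)
  expect_equal(reached_length(all_r), sum(net$edges$length_m))
})

test_that("loop-reached portions merge without double counting", {
  # square loop, 4 x 300 m
  nodes <- tibble::tibble(node_id = 1:4,
                          x = c(0, 300, 300, 0), y = c(0, 0, 300, 300))
  edges <- tibble::tibble(edge_id = 1:4, u = c(1, 2, 3, 1),
                          v = c(2, 3, 4, 4))
  net <- load_network(nodes, edges)
  origin <- tibble::tibble(edge_id = 1, offset_m = 150)
  for (cutoff in c(200, 450, 600, 1200)) {
    got <- reached_length(reachable_network(net, origin, cutoff))
    ora <- oracle_reached_length(net, origin, cutoff, step = 0.25)
    expect_equal(got, ora, tolerance = 1)
  }
  # with a cutoff covering everything the loop is counted exactly once
  expect_equal(reached_length(reachable_network(net, origin, 1200)), 1200)
})

test_that("catchment cells follow the half-open positive-overlap rule", {
  region <- square_region(1000)
  grid <- build_square_grid(region)

  # a segment fully inside one cell touches exactly that cell
  nodes <- tibble::tibble(node_id = 1:2, x = c(60, 180), y = c(60, 60))
  net <- load_network(nodes, tibble::tibble(edge_id = 1, u = 1, v = 2))
  reached <- tibble::tibble(edge_id = 1, from_m = 0, to_m = 120)
  expect_length(catchment_cells(net, reached, grid), 1)

  # 300 m eastward from a cell corner crosses two cells
  nodes <- tibble::tibble(node_id = 1:2, x = c(0, 300), y = c(0, 0))
  net <- load_network(nodes, tibble::tibble(edge_id = 1, u = 1, v = 2))
  reached <- tibble::tibble(edge_id = 1, from_m = 0, to_m = 300)
  expect_length(catchment_cells(net, reached, grid), 2)

  # empty reached set: empty with warning
  expect_warning(
    out <- catchment_cells(net, reached[0, ], grid),
    "empty"
  )
  expect_length(out, 0)
})

test_that("catchment cells equal the brute-force sampling oracle", {
  region <- square_region(1000)
  grid <- build_square_grid(region)
  for (seed in c(41, 42)) {
    net <- make_random_net(seed, n = 30)
    origin <- tibble::tibble(edge_id = net$edges$edge_id[2],
                             offset_m = net$edges$length_m[2] / 3)
    reached <- reachable_network(net, origin, cutoff = 600)
    got <- catchment_cells(net, reached, grid)
    ora <- oracle_catchment_cells(net, reached, grid)
    expect_equal(got, ora)
  }
})

test_that("catchment summary computes densities exactly", {
  net <- make_path_net(2, edge_len = 250)
  region <- region_boundary(list(x = c(0, 500, 500, 0),
                                 y = c(-125, -125, 125, 125)))
  grid <- build_square_grid(region)
  grid$population <- c(100, 200)
  origin <- tibble::tibble(point_id = 1L, edge_id = 1, offset_m = 100)
  cs <- catchment_summary(net, origin, cells = c(1, 2), grid,
                          cutoff = 1000)
  expect_equal(cs$area_km2, 0.125)
  expect_equal(cs$population, 300)
  expect_equal(cs$pop_density, 2400)

  grid$population <- c(0, 0)
  cs0 <- catchment_summary(net, origin, cells = c(1, 2), grid, 1000)
  expect_equal(cs0$pop_density, 0)
  expect_error(catchment_summary(net, origin, integer(0), grid, 1000),
               "no cells")
})

test_that("intersection counts equal the distance-oracle enumeration", {
  spec <- city_spec(seed = 2, extent_m = 2000, block_m = 250)
  net <- generate_street_network(spec)
  region <- synthetic_region(spec)
  grid <- build_square_grid(region)
  grid$population <- 1
  # an interior edge origin
  mid_edge <- net$edges[net$edges$u == 41, ][1, ]
  origin <- tibble::tibble(point_id = 1L, edge_id = mid_edge$edge_id,
                           offset_m = 100)
  cs <- walkable_catchment(net, origin, grid, cutoff = 1000)
  ora_d <- oracle_origin_distances(net, origin$edge_id, origin$offset_m)
  expected <- sum(net$nodes$degree >= 3 &
                    ora_d[as.character(net$nodes$node_id)] <= 1000)
  expect_equal(cs$intersections, expected)
})

test_that("catchments grow monotonically with the cutoff", {
  net <- make_random_net(51, n = 40)
  region <- square_region(1000)
  grid <- build_square_grid(region)
  origin <- tibble::tibble(edge_id = net$edges$edge_id[5],
                           offset_m = net$edges$length_m[5] / 2)
  prev_cells <- integer(0)
  prev_len <- 0
  for (cutoff in c(150, 300, 600, 1200)) {
    reached <- reachable_network(net, origin, cutoff)
    cells <- catchment_cells(net, reached, grid)
    len <- reached_length(reached)
    expect_true(all(prev_cells %in% cells))
    expect_gte(len, prev_len)
    prev_cells <- cells
    prev_len <- len
  }
})

test_that("cell-union area contains a sausage buffer of the reached streets", {
  net <- make_random_net(61, n = 30)
  region <- square_region(1000)
  grid <- build_square_grid(region)
  origin <- tibble::tibble(edge_id = net$edges$edge_id[1],
                           offset_m = net$edges$length_m[1] / 2)
  reached <- reachable_network(net, origin, cutoff = 500)
  cells <- catchment_cells(net, reached, grid)
  cell_area <- length(cells) * 0.0625 * 1e6
  # Monte Carlo area of the radius-50 m buffer around reached segments
  p1 <- walkshed:::edge_point(net, reached$edge_id, reached$from_m)
  p2 <- walkshed:::edge_point(net, reached$edge_id, reached$to_m)
  withr::with_seed(1, {
    sx <- stats::runif(4000, 0, 1000)
    sy <- stats::runif(4000, 0, 1000)
  })
  inside <- rep(FALSE, length(sx))
  for (i in seq_len(nrow(reached))) {
    pr <- walkshed:::project_point_segment(sx, sy, p1$x[i], p1$y[i],
                                           p2$x[i], p2$y[i])
    inside <- inside | pr$dist <= 50
  }
  buffer_area <- mean(inside) * 1e6
  expect_gte(cell_area, buffer_area * 0.95)  # MC slack
})
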