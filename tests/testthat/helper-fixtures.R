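# Shared fixtures, all built in code at test time.

# Straight path network: n_edges edges of edge_len metres along the x axis.
make_path_net <- function(n_edges = 4, edge_len = 300) {
  nodes <- tibble::tibble(node_id = seq_len(n_edges + 1),
                          x = (seq_len(n_edges + 1) - 1) * edge_len, y = 0)
  edges <- tibble::tibble(edge_id = seq_len(n_edges),
                          u = seq_len(n_edges), v = seq_len(n_edges) + 1)
  load_network(nodes, edges)
}

# Random connected planar-ish network: n random points, each joined to its
# k nearest neighbours, reduced to the largest component.
make_random_net <- function(seed, n = 30, extent = 1000, k = 3) {
  withr::with_seed(seed, {
    x <- stats::runif(n, 0, extent)
    y <- stats::runif(n, 0, extent)
  })
  edges <- list()
  for (i in seq_len(n)) {
    d <- sqrt((x - x[i])^2 + (y - y[i])^2)
    nb <- order(d)[2:(k + 1)]
    for (j in nb) {
      edges[[length(edges) + 1L]] <- c(min(i, j), max(i, j))
    }
  }
  em <- unique(do.call(rbind, edges))
  nodes <- tibble::tibble(node_id = seq_len(n), x = x, y = y)
  edges <- tibble::tibble(edge_id = seq_len(nrow(em)),
                          u = em[, 1], v = em[, 2])
  largest_component(load_network(nodes, edges))
}

# A long thin "ribbon" city with a single street, uniform population, and
# food markets planted so that exactly a fraction p of the street length
# lies within 500 m of a market. Used for planted-parameter recovery.
make_ribbon_city <- function(p, total_len = 12000, node_step = 200,
                             pop_per_cell = 10) {
  n_nodes <- total_len / node_step + 1
  nodes <- tibble::tibble(node_id = seq_len(n_nodes),
                          x = (seq_len(n_nodes) - 1) * node_step, y = 0)
  edges <- tibble::tibble(edge_id = seq_len(n_nodes - 1),
                          u = seq_len(n_nodes - 1),
                          v = seq_len(n_nodes - 1) + 1)
  net <- load_network(nodes, edges)
  region <- region_boundary(list(x = c(0, total_len, total_len, 0),
                                 y = c(-125, -125, 125, 125)),
                            name = sprintf("ribbon-%g", p))
  grid <- build_square_grid(region)
  grid$population <- pop_per_cell
  k <- round(p * total_len / 1000)
  layers <- list()
  if (k > 0) {
    markets <- tibble::tibble(dest_id = seq_len(k),
                              x = 500 + 1000 * (seq_len(k) - 1), y = 0)
    layers$food_market <- snap_to_network(net, markets, "food_market")
  } else {
    layers$food_market <- destination_layer(
      tibble::tibble(dest_id = integer(), x = numeric(), y = numeric(),
                     edge_id = integer(), offset_m = numeric(),
                     snap_dist = numeric()),
      "food_market"
    )
  }
  list(net = net, region = region, grid = grid, layers = layers)
}

# Hand-written minimal GTFS feed with explicit departure times at one stop.
write_mini_gtfs <- function(dir, departures = c("08:00:00", "08:20:00",
                                                "08:40:00"),
                            weekdays = c(1, 1, 1, 1, 1),
                            stop_id = "S1") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, f) utils::write.csv(df, file.path(dir, f),
                                         row.names = FALSE, quote = FALSE)
  wr(data.frame(stop_id = stop_id, stop_name = stop_id,
                stop_lat = 0, stop_lon = 0), "stops.txt")
  wr(data.frame(route_id = "R1", service_id = "WD",
                trip_id = paste0("T", seq_along(departures))), "trips.txt")
  wr(data.frame(trip_id = paste0("T", seq_along(departures)),
                arrival_time = departures, departure_time = departures,
                stop_id = stop_id,
                stop_sequence = 1), "stop_times.txt")
  wr(data.frame(service_id = "WD", monday = weekdays[1],
                tuesday = weekdays[2], wednesday = weekdays[3],
                thursday = weekdays[4], friday = weekdays[5],
                saturday = 0, sunday = 0,
                start_date = "20150105", end_date = "20151231"),
     "calendar.txt")
  dir
}

# Square test region [0, side]^2.
square_region <- function(side = 1000, name = "sq") {
  region_boundary(list(x = c(0, side, side, 0), y = c(0, 0, side, side)),
                  name = name)
}
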