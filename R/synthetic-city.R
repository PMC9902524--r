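# Deterministic synthetic study regions: street network, population grid,
# destination layers, open-space polygons and a GTFS feed, all driven by a
# single integer seed. Every downstream stage of the pipeline is testable
# on these without any external downloads.
#
# One named pseudo-random stream per layer (network, population, each
# destination class, open space) is derived from the seed, so adding or
# regenerating one layer never perturbs the others.

#' Specify a synthetic city
#'
#' Defaults describe a compact mid-sized test city: a 2 km square with
#' 250 m blocks, 20,000 residents decaying radially from the centre
#' (rate 1/km), a handful of clustered amenities, mixed-size open spaces
#' and a 20 min fixed-headway weekday transit service.
#'
#' @param seed Integer seed driving all layer streams.
#' @param layout `"grid"` (regular lattice) or `"organic"` (perturbed
#'   lattice with a fraction of edges removed, connectivity preserved).
#' @param extent_m Side of the square region in metres (>= 4 blocks).
#' @param block_m Target block spacing in metres.
#' @param pop_total Total population (nonnegative integer).
#' @param pop_gradient Radial exponential decay rate of expected population
#'   density, per km (0 = uniform).
#' @param n_food,n_convenience,n_stops Destination counts per class.
#' @param pos_areas_ha Vector of open-space areas to generate, hectares.
#' @param transit_headway_min Fixed weekday headway in minutes.
#' @param cluster_factor Amenity clustering strength in `[0, 1]` (0 =
#'   uniform along the network, 1 = fully clustered).
#' @param edge_removal Fraction of lattice edges removed in the `organic`
#'   layout (connectivity is never broken).
#' @param noise_factor Node-position noise amplitude for `organic`, as a
#'   fraction of `block_m` (capped at 0.3).
#' @return A validated `city_spec` list.
#' @export
city_spec <- function(seed = 1L,
                      layout = c("grid", "organic"),
                      extent_m = 2000,
                      block_m = 250,
                      pop_total = 20000,
                      pop_gradient = 1,
                      n_food = 8L,
                      n_convenience = 8L,
                      n_stops = 12L,
                      pos_areas_ha = c(0.5, 1, 2, 3),
                      transit_headway_min = 20,
                      cluster_factor = 0.5,
                      edge_removal = 0.2,
                      noise_factor = 0.3) {
  layout <- match.arg(layout)
  if (extent_m < 4 * block_m) {
    stop("extent_m must be at least 4 blocks", call. = FALSE)
  }
  if (floor(extent_m / block_m) < 2) {
    stop("extent/block combination yields fewer than 2x2 blocks",
         call. = FALSE)
  }
  if (pop_total < 0 || n_food < 0 || n_convenience < 0 || n_stops < 0) {
    stop("counts must be nonnegative", call. = FALSE)
  }
  if (cluster_factor < 0 || cluster_factor > 1) {
    stop("cluster_factor must be in [0, 1]", call. = FALSE)
  }
  if (transit_headway_min <= 0) {
    stop("transit_headway_min must be positive", call. = FALSE)
  }
  structure(list(
    seed = as.integer(seed), layout = layout,
    extent_m = extent_m, block_m = block_m,
    pop_total = as.integer(pop_total), pop_gradient = pop_gradient,
    n_food = as.integer(n_food), n_convenience = as.integer(n_convenience),
    n_stops = as.integer(n_stops), pos_areas_ha = pos_areas_ha,
    transit_headway_min = transit_headway_min,
    cluster_factor = cluster_factor,
    edge_removal = min(max(edge_removal, 0), 0.9),
    noise_factor = min(max(noise_factor, 0), 0.3)
  ), class = "city_spec")
}

# independent deterministic sub-seed per named layer
stream_seed <- function(seed, layer) {
  idx <- match(layer, c("network", "population", "food_market",
                        "convenience", "pt_stop", "pos", "gtfs"))
  if (is.na(idx)) stop("unknown stream: ", layer, call. = FALSE)
  (abs(seed) * 7L + idx * 9973L) %% 2147483629L
}

#' Square region boundary of a synthetic city
#'
#' @param spec A `city_spec`.
#' @return A `region_boundary` covering `[0, extent_m]^2`.
#' @export
synthetic_region <- function(spec) {
  region_boundary(rect_ring(0, 0, spec$extent_m, spec$extent_m),
                  name = sprintf("synthetic-%d", spec$seed))
}

#' Generate the synthetic street network
#'
#' `grid` layout: a regular lattice with `block_m` spacing covering the
#' extent. `organic` layout: the same lattice with node positions perturbed
#' by seeded radial noise (at most `noise_factor * block_m`) and a seeded
#' fraction of edges removed, skipping any removal that would disconnect
#' the network. Identical specs yield identical networks.
#'
#' @param spec A `city_spec`.
#' @return A connected `street_network`.
#' @export
generate_street_network <- function(spec) {
  n_side <- floor(spec$extent_m / spec$block_m) + 1L
  ids <- seq_len(n_side^2)
  col <- (ids - 1L) %% n_side
  row <- (ids - 1L) %/% n_side
  nodes <- tibble::tibble(node_id = ids,
                          x = col * spec$block_m,
                          y = row * spec$block_m)
  h <- which(col < n_side - 1L)
  v <- which(row < n_side - 1L)
  edges <- tibble::tibble(
    u = c(ids[h], ids[v]),
    v = c(ids[h] + 1L, ids[v] + n_side)
  )
  edges$edge_id <- seq_len(nrow(edges))
  if (spec$layout == "organic") {
    withr::with_seed(stream_seed(spec$seed, "network"), {
      r <- stats::runif(n_side^2, 0, spec$noise_factor * spec$block_m)
      th <- stats::runif(n_side^2, 0, 2 * pi)
      nodes$x <- nodes$x + r * cos(th)
      nodes$y <- nodes$y + r * sin(th)
      target <- floor(spec$edge_removal * nrow(edges))
      order_ <- sample.int(nrow(edges))
      keep <- rep(TRUE, nrow(edges))
      removed <- 0L
      for (e in order_) {
        if (removed >= target) break
        # candidate graph without edge e among the kept edges
        cand <- keep
        cand[e] <- FALSE
        g2 <- igraph::graph_from_data_frame(
          data.frame(from = edges$u[cand], to = edges$v[cand]),
          directed = FALSE, vertices = data.frame(name = ids)
        )
        if (igraph::is_connected(g2)) {
          keep <- cand
          removed <- removed + 1L
        }
      }
      edges <- edges[keep, , drop = FALSE]
      edges$edge_id <- seq_len(nrow(edges))
    })
  }
  load_network(nodes, edges[, c("edge_id", "u", "v")])
}

#' Generate the synthetic population grid
#'
#' Tiles the region with 250 m cells and distributes `pop_total` people
#' over them by a seeded multinomial draw whose expected weights decay
#' exponentially with distance from the region centre
#' (`exp(-pop_gradient * r_km)`). Total population is conserved exactly.
#'
#' @param spec A `city_spec`.
#' @param region Optional `region_boundary` (default the full synthetic
#'   extent).
#' @param cell_size Cell size in metres (default 250).
#' @return A population grid tibble (see [build_square_grid()]).
#' @export
generate_population_grid <- function(spec, region = synthetic_region(spec),
                                     cell_size = 250) {
  grid <- build_square_grid(region, cell_size)
  cx <- (grid$xmin + grid$xmax) / 2
  cy <- (grid$ymin + grid$ymax) / 2
  ctr <- c(mean(range(region$x)), mean(range(region$y)))
  r_km <- sqrt((cx - ctr[1])^2 + (cy - ctr[2])^2) / 1000
  w <- exp(-spec$pop_gradient * r_km)
  pops <- withr::with_seed(
    stream_seed(spec$seed, "population"),
    as.integer(stats::rmultinom(1, spec$pop_total, w))
  )
  grid$population <- pops
  grid
}

#' Generate synthetic destination layers
#'
#' Places the requested number of points per class on (or within 20 m of)
#' network edges. With probability `cluster_factor` a point is drawn near
#' one of three seeded cluster centres; otherwise uniformly along the
#' network (edges weighted by length). Open spaces are axis-aligned
#' rectangles matching the requested areas to within 5%.
#'
#' @param spec A `city_spec`.
#' @param net The city's `street_network`.
#' @return Named list: `food_market`, `convenience`, `pt_stop` (raw point
#'   tibbles with `dest_id`, `x`, `y`) and `pos` (rectangle tibble with
#'   `pos_id`, bounds and `area_ha`).
#' @export
generate_destinations <- function(spec, net) {
  if (nrow(net$edges) == 0) stop("empty network", call. = FALSE)
  total_len <- sum(net$edges$length_m)
  counts <- c(food_market = spec$n_food, convenience = spec$n_convenience,
              pt_stop = spec$n_stops)
  if (any(counts > floor(total_len))) {
    stop("requested destination count exceeds available placement sites",
         call. = FALSE)
  }
  iu <- match(net$edges$u, net$nodes$node_id)
  iv <- match(net$edges$v, net$nodes$node_id)
  midx <- (net$nodes$x[iu] + net$nodes$x[iv]) / 2
  midy <- (net$nodes$y[iu] + net$nodes$y[iv]) / 2
  out <- list()
  for (cls in names(counts)) {
    n <- counts[[cls]]
    out[[cls]] <- withr::with_seed(stream_seed(spec$seed, cls), {
      # cluster centres: seeded nodes; pull scale ~ one block
      ctr_nodes <- sample(nrow(net$nodes), min(3L, nrow(net$nodes)))
      if (n == 0) {
        tibble::tibble(dest_id = integer(), x = numeric(), y = numeric())
      } else {
        xs <- numeric(n); ys <- numeric(n)
        for (i in seq_len(n)) {
          clustered <- stats::runif(1) < spec$cluster_factor
          if (clustered) {
            ctr <- ctr_nodes[sample.int(length(ctr_nodes), 1)]
            d2 <- (midx - net$nodes$x[ctr])^2 + (midy - net$nodes$y[ctr])^2
            wts <- exp(-sqrt(d2) / (0.75 * spec$block_m))
          } else {
            wts <- net$edges$length_m
          }
          e <- sample.int(nrow(net$edges), 1, prob = wts)
          t <- stats::runif(1)
          ex <- net$nodes$x[iu[e]] + t * (net$nodes$x[iv[e]] - net$nodes$x[iu[e]])
          ey <- net$nodes$y[iu[e]] + t * (net$nodes$y[iv[e]] - net$nodes$y[iu[e]])
          # perpendicular jitter keeps the point within 20 m of its edge
          ang <- atan2(net$nodes$y[iv[e]] - net$nodes$y[iu[e]],
                       net$nodes$x[iv[e]] - net$nodes$x[iu[e]]) + pi / 2
          jit <- stats::runif(1, -20, 20)
          xs[i] <- ex + jit * cos(ang)
          ys[i] <- ey + jit * sin(ang)
        }
        tibble::tibble(dest_id = seq_len(n), x = xs, y = ys)
      }
    })
  }
  out$pos <- withr::with_seed(stream_seed(spec$seed, "pos"), {
    areas <- spec$pos_areas_ha
    if (!length(areas)) {
      tibble::tibble(pos_id = integer(), xmin = numeric(), ymin = numeric(),
                     xmax = numeric(), ymax = numeric(), area_ha = numeric())
    } else {
      rows <- lapply(seq_along(areas), function(i) {
        a_m2 <- areas[i] * 1e4 * stats::runif(1, 0.955, 1.045)
        aspect <- stats::runif(1, 0.5, 2)
        w <- sqrt(a_m2 * aspect)
        h <- a_m2 / w
        cx <- stats::runif(1, w / 2, max(w / 2, spec$extent_m - w / 2))
        cy <- stats::runif(1, h / 2, max(h / 2, spec$extent_m - h / 2))
        tibble::tibble(pos_id = i,
                       xmin = cx - w / 2, ymin = cy - h / 2,
                       xmax = cx + w / 2, ymax = cy + h / 2,
                       area_ha = w * h / 1e4)
      })
      dplyr::bind_rows(rows)
    }
  })
  out
}

#' Write a minimal GTFS feed for a synthetic city
#'
#' One route serves every stop with a fixed weekday headway between 06:00
#' and 22:00 (so `16 * 60 / headway + 1` departures per stop); Saturday and
#' Sunday have no service. The feed round-trips through [parse_gtfs()] with
#' stop coordinates in the planar analysis CRS.
#'
#' @param spec A `city_spec`.
#' @param stops Tibble with `dest_id` (or `stop_id`), `x`, `y`.
#' @param out_dir Directory to write the feed into (created if needed).
#' @return `out_dir`, invisibly.
#' @export
generate_gtfs <- function(spec, stops, out_dir) {
  if (!nrow(stops)) stop("need at least one stop", call. = FALSE)
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) {
    stop("cannot create GTFS directory: ", out_dir, call. = FALSE)
  }
  sid <- if ("stop_id" %in% names(stops)) {
    as.character(stops$stop_id)
  } else {
    sprintf("S%03d", stops$dest_id)
  }
  wr <- function(df, f) {
    utils::write.csv(df, file.path(out_dir, f), row.names = FALSE,
                     quote = FALSE)
  }
  wr(data.frame(agency_id = "SYN", agency_name = "Synthetic Transit",
                agency_url = "https://example.org",
                agency_timezone = "Etc/UTC"), "agency.txt")
  wr(data.frame(stop_id = sid, stop_name = sid,
                stop_lat = stops$y, stop_lon = stops$x), "stops.txt")
  wr(data.frame(route_id = "R1", agency_id = "SYN", route_short_name = "1",
                route_long_name = "Loop", route_type = 3), "routes.txt")
  starts <- seq(6 * 3600, 22 * 3600, by = spec$transit_headway_min * 60)
  trip_ids <- sprintf("T%04d", seq_along(starts))
  wr(data.frame(route_id = "R1", service_id = "WD", trip_id = trip_ids),
     "trips.txt")
  fmt <- function(s) {
    sprintf("%02d:%02d:%02d", s %/% 3600, (s %% 3600) %/% 60, s %% 60)
  }
  n_stop <- length(sid)
  st <- data.frame(
    trip_id = rep(trip_ids, each = n_stop),
    arrival_time = fmt(rep(starts, each = n_stop) + 30 * (seq_len(n_stop) - 1)),
    departure_time = fmt(rep(starts, each = n_stop) + 30 * (seq_len(n_stop) - 1)),
    stop_id = rep(sid, times = length(starts)),
    stop_sequence = rep(seq_len(n_stop), times = length(starts))
  )
  wr(st, "stop_times.txt")
  wr(data.frame(service_id = "WD", monday = 1, tuesday = 1, wednesday = 1,
                thursday = 1, friday = 1, saturday = 0, sunday = 0,
                start_date = "20150105", end_date = "20151231"),
     "calendar.txt")
  invisible(out_dir)
}

#' Generate a complete synthetic city
#'
#' Orchestrates the per-layer generators; optionally writes all layers
#' (GeoJSON + GTFS + manifest) to `dir`.
#'
#' @param spec A `city_spec`.
#' @param dir Optional output directory.
#' @return List with `spec`, `region`, `network`, `grid`, `destinations`
#'   (raw layers incl. `pos`) and, when `dir` is given, `gtfs_dir`.
#' @export
generate_city <- function(spec, dir = NULL) {
  region <- synthetic_region(spec)
  net <- generate_street_network(spec)
  grid <- generate_population_grid(spec, region)
  dest <- generate_destinations(spec, net)
  out <- list(spec = spec, region = region, network = net, grid = grid,
              destinations = dest)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_geojson_points(net$nodes, file.path(dir, "nodes.geojson"))
    utils::write.csv(net$edges, file.path(dir, "edges.csv"),
                     row.names = FALSE)
    utils::write.csv(grid, file.path(dir, "population_grid.csv"),
                     row.names = FALSE)
    for (cls in c("food_market", "convenience", "pt_stop")) {
      write_geojson_points(dest[[cls]],
                           file.path(dir, paste0(cls, ".geojson")))
    }
    write_geojson_polygons(
      lapply(seq_len(nrow(dest$pos)), function(i) {
        rect_ring(dest$pos$xmin[i], dest$pos$ymin[i],
                  dest$pos$xmax[i], dest$pos$ymax[i])
      }),
      dest$pos, file.path(dir, "open_space.geojson")
    )
    if (nrow(dest$pt_stop)) {
      out$gtfs_dir <- file.path(dir, "gtfs")
      generate_gtfs(spec, dest$pt_stop, out$gtfs_dir)
    }
    jsonlite::write_json(unclass(spec), file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}
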