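# End-to-end per-city analysis: sample points -> catchment densities ->
# destination access -> composite indicators -> hexagon neighbourhoods ->
# city summary; plus multi-city pooling for between-city comparison.

#' Analyse one city
#'
#' Runs the full point-level pipeline on a street network: generates 30 m
#' sample points in populated cells, computes each point's 1000 m walkable
#' catchment densities, binary 500 m access per destination layer, the
#' daily living score and the within-city walkability index, then
#' aggregates to hexagon neighbourhoods and a population-weighted city
#' summary row.
#'
#' @param net A `street_network` (reduced to its largest component
#'   internally when disconnected).
#' @param grid Population grid ([build_square_grid()] /
#'   [generate_population_grid()]).
#' @param region A `region_boundary` (used to build the hex layer).
#' @param layers Named list of snapped `destination_layer`s; recognised
#'   names: `food_market`, `convenience`, `pt_stop_any`, `pt_stop_30min`,
#'   `pt_stop_20min`, `pos_any_entry`, `pos_large_entry`. Missing classes
#'   yield `NA` indicator columns (excluded from group means downstream).
#' @param city City name for the summary row.
#' @param income_group Optional benchmark label (`"middle"`/`"high"`).
#' @param config List of tunables: `sample_interval` (30), `cutoff` (1000),
#'   `access_threshold` (500), `distance_cap` (3200), `hex_width` (250),
#'   `scenarios` (A and B), `pm25_transport` (NA passthrough).
#' @return List with `points` (indicator records), `hexes`
#'   ([aggregate_to_hex()] output), `city` ([city_percentages()] row),
#'   `net`, `grid`, `hex_layer`.
#' @export
analyse_city <- function(net, grid, region, layers = list(),
                         city = "city", income_group = NA_character_,
                         config = list()) {
  cfg <- utils::modifyList(list(
    sample_interval = 30, cutoff = 1000, access_threshold = 500,
    distance_cap = 3200, hex_width = 250,
    scenarios = list(threshold_scenario("A"), threshold_scenario("B")),
    pm25_transport = NA_real_
  ), config)
  if (igraph::count_components(net$graph) > 1) {
    net <- largest_component(net)
  }
  hex_layer <- build_hex_grid(region, cfg$hex_width)
  pts <- generate_sample_points(net, cfg$sample_interval, grid, hex_layer)
  if (!nrow(pts)) stop("no sample points in populated cells", call. = FALSE)
  dmat <- network_distance_matrix(net)
  n <- nrow(pts)
  cat_rows <- vector("list", n)
  class_cols <- c(food_market = "access_food", convenience = "access_convenience",
                  pt_stop_any = "access_pt_any", pt_stop_30min = "access_pt_30",
                  pt_stop_20min = "access_pt_20", pos_any_entry = "access_pos_any",
                  pos_large_entry = "access_pos_large")
  acc <- matrix(NA_integer_, n, length(class_cols),
                dimnames = list(NULL, class_cols))
  dist_m <- matrix(NA_real_, n, length(class_cols),
                   dimnames = list(NULL, paste0("dist_", names(class_cols))))
  for (i in seq_len(n)) {
    origin <- pts[i, ]
    cat_rows[[i]] <- walkable_catchment(net, origin, grid, cfg$cutoff, dmat)
    for (k in seq_along(class_cols)) {
      lyr <- layers[[names(class_cols)[k]]]
      if (is.null(lyr)) next
      nd <- withCallingHandlers(
        nearest_distance(net, origin, lyr, cfg$distance_cap, dmat),
        warning = function(w) invokeRestart("muffleWarning")
      )
      dist_m[i, k] <- nd$distance_m
      acc[i, k] <- binary_access(nd$distance_m, cfg$access_threshold,
                                 nd$censored)
    }
  }
  catch <- dplyr::bind_rows(cat_rows)
  pts <- dplyr::bind_cols(
    pts,
    catch[, c("n_cells", "area_km2", "population", "intersections",
              "pop_density", "int_density")],
    tibble::as_tibble(acc),
    tibble::as_tibble(dist_m)
  )
  pts$daily_living <- if (all(!is.na(acc[, "access_pt_any"]))) {
    daily_living_score(pts$access_food, pts$access_convenience,
                       pts$access_pt_any)
  } else {
    NA_integer_
  }
  if (!all(is.na(pts$daily_living))) {
    z_pop <- standardise(pts$pop_density)
    z_int <- standardise(pts$int_density)
    z_dl <- standardise(pts$daily_living)
    pts$walkability_within <- walkability(z_pop, z_int, z_dl)
  } else {
    pts$walkability_within <- NA_real_
  }
  hexes <- aggregate_to_hex(pts, hex_layer, grid)
  city_row <- city_percentages(hexes, city, income_group,
                               scenarios = cfg$scenarios,
                               pm25_transport = cfg$pm25_transport)
  list(points = pts, hexes = hexes, city = city_row, net = net,
       grid = grid, hex_layer = hex_layer)
}

#' Compare several analysed cities
#'
#' Pools the hexagon neighbourhoods of all cities and standardises
#' population density, intersection density and the daily living score
#' against the pooled distribution, yielding a between-city walkability
#' index per hexagon (zero = global average). Also stacks the city summary
#' rows and computes income-group benchmark rows.
#'
#' @param runs Named list of [analyse_city()] results (names = cities).
#' @return List with `hexes` (pooled hex table with `walkability_between`),
#'   `cities` (stacked summary rows) and `groups` ([group_summary()]).
#' @export
compare_cities <- function(runs) {
  stopifnot(length(runs) >= 1)
  hx <- dplyr::bind_rows(lapply(names(runs), function(nm) {
    h <- runs[[nm]]$hexes
    h$city <- nm
    h
  }))
  for (col in c("pop_density", "int_density", "daily_living")) {
    hx[[paste0("z_", col)]] <- standardise(hx[[col]])
  }
  hx$walkability_between <- walkability(hx$z_pop_density, hx$z_int_density,
                                        hx$z_daily_living)
  cities <- dplyr::bind_rows(lapply(runs, function(r) r$city))
  groups <- group_summary(cities)
  list(hexes = hx, cities = cities, groups = groups)
}

#' Build all destination layers for a synthetic city
#'
#' Convenience wrapper: snaps the generated amenity points, derives
#' open-space entry points, and (when a GTFS directory is given) computes
#' headway-classed transit stop layers.
#'
#' @param cityobj Output of [generate_city()].
#' @param gtfs_dir Optional GTFS directory (e.g. `cityobj$gtfs_dir`).
#' @param tolerance Snap tolerance in metres.
#' @return Named list of snapped layers suitable for [analyse_city()].
#' @export
build_city_layers <- function(cityobj, gtfs_dir = NULL, tolerance = 500) {
  net <- cityobj$network
  dest <- cityobj$destinations
  layers <- list()
  if (nrow(dest$food_market)) {
    layers$food_market <- snap_to_network(net, dest$food_market,
                                          "food_market", tolerance)
  }
  if (nrow(dest$convenience)) {
    layers$convenience <- snap_to_network(net, dest$convenience,
                                          "convenience", tolerance)
  }
  if (!is.null(gtfs_dir)) {
    feed <- parse_gtfs(gtfs_dir)
    hw <- stop_headways(feed, representative_weekday(feed))
    layers <- c(layers, transit_stop_layers(feed, hw, net, tolerance))
  } else if (nrow(dest$pt_stop)) {
    layers$pt_stop_any <- snap_to_network(net, dest$pt_stop, "pt_stop_any",
                                          tolerance)
  }
  if (nrow(dest$pos)) {
    layers <- c(layers, pos_entry_points(dest$pos, net,
                                         tolerance = tolerance))
  }
  layers
}
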