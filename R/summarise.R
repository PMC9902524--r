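# Aggregation: sample points -> hexagon neighbourhoods -> city-level
# population-weighted summaries -> income-group benchmark rows.

#' Aggregate point indicators to hexagon neighbourhoods
#'
#' Unweighted means of every numeric indicator over the sample points in
#' each hexagon; hexagons containing no points are omitted. The mean of a
#' binary access column is the fraction of the hexagon's sampled walkable
#' area with access.
#'
#' @param points Tibble of point indicators carrying `hex_id` and numeric
#'   indicator columns.
#' @param hexes Hex layer from [build_hex_grid()] (for centroids; optional).
#' @param grid Optional population grid; when given, each cell's population
#'   is assigned to the hexagon containing the cell centroid and summed per
#'   hexagon into a `population` column.
#' @return A tibble keyed by `hex_id` with `n_points`, per-indicator means,
#'   `pos_large_access` (see [hex_pos_access()]) and optionally
#'   `population`.
#' @export
aggregate_to_hex <- function(points, hexes = NULL, grid = NULL) {
  stopifnot("hex_id" %in% names(points))
  num_cols <- setdiff(
    names(points)[vapply(points, is.numeric, logical(1))],
    c("point_id", "edge_id", "offset_m", "x", "y", "cell_id", "hex_id")
  )
  out <- dplyr::summarise(
    dplyr::group_by(points, .data$hex_id),
    n_points = dplyr::n(),
    dplyr::across(dplyr::all_of(num_cols), ~ mean(.x)),
    .groups = "drop"
  )
  if ("access_pos_large" %in% names(out)) {
    out$pos_large_access <- hex_pos_access(out$access_pos_large)
  }
  if (!is.null(grid) && !is.null(hexes)) {
    ccx <- (grid$xmin + grid$xmax) / 2
    ccy <- (grid$ymin + grid$ymax) / 2
    cell_hex <- assign_hex(ccx, ccy, hexes)
    pop <- tapply(grid$population, cell_hex, sum)
    out$population <- as.numeric(pop[as.character(out$hex_id)])
    out$population[is.na(out$population)] <- 0
  }
  if (!is.null(hexes)) {
    idx <- match(out$hex_id, hexes$hex_id)
    out$cx <- hexes$cx[idx]
    out$cy <- hexes$cy[idx]
  }
  dplyr::arrange(out, .data$hex_id)
}

#' Hexagon-level large-open-space access
#'
#' A neighbourhood is considered to have access when at least half of its
#' sampled walkable area (its sample points) lies within the access
#' threshold of a large public open space.
#'
#' @param mean_binary Per-hex mean of the point-level binary scores.
#' @return Integer 0/1 vector.
#' @export
hex_pos_access <- function(mean_binary) {
  as.integer(mean_binary >= 0.5)
}

#' City-level population-weighted indicator summary
#'
#' For every access indicator, the percentage of the city's population
#' living with access: `100 * sum(pop_h * mean_h) / sum(pop_h)` over
#' hexagons. Scenario exposure is the percentage of population living in
#' hexagons whose mean density reaches or exceeds each scenario threshold.
#'
#' @param hex_summary Output of [aggregate_to_hex()] including `population`.
#' @param city City name.
#' @param income_group `"middle"` or `"high"` (optional benchmark label).
#' @param scenarios List of [threshold_scenario()]s (defaults: A and B).
#' @param pm25_transport Optional citywide transport-sector PM2.5 emission
#'   scalar (tonnes/year), passed through to the summary row.
#' @return One-row tibble of percentages (`pct_*`), scenario exposures
#'   (`pct_scenario<X>_pop`, `pct_scenario<X>_int`) and passthrough fields.
#' @export
city_percentages <- function(hex_summary, city = "city",
                             income_group = NA_character_,
                             scenarios = list(threshold_scenario("A"),
                                              threshold_scenario("B")),
                             pm25_transport = NA_real_) {
  if (!"population" %in% names(hex_summary)) {
    stop("hex summary must carry populations (aggregate_to_hex(grid=))",
         call. = FALSE)
  }
  w <- hex_summary$population
  if (sum(w) <= 0) stop("total population is zero", call. = FALSE)
  wmean <- function(col) {
    if (!col %in% names(hex_summary)) return(NA_real_)
    100 * sum(w * hex_summary[[col]]) / sum(w)
  }
  out <- tibble::tibble(
    city = city,
    income_group = income_group,
    pct_access_food = wmean("access_food"),
    pct_access_convenience = wmean("access_convenience"),
    pct_access_pt_any = wmean("access_pt_any"),
    pct_access_pt_30min = wmean("access_pt_30"),
    pct_access_pt_20min = wmean("access_pt_20"),
    pct_access_pos_any = wmean("access_pos_any"),
    pct_access_pos_large = wmean("access_pos_large")
  )
  for (sc in scenarios) {
    meets <- scenario_flags(hex_summary$pop_density,
                            hex_summary$int_density, sc)
    out[[paste0("pct_scenario", sc$name, "_pop")]] <-
      100 * sum(w * meets$meets_pop) / sum(w)
    out[[paste0("pct_scenario", sc$name, "_int")]] <-
      100 * sum(w * meets$meets_int) / sum(w)
  }
  out$pm25_transport <- pm25_transport
  out
}

#' Group summary rows (benchmarking)
#'
#' Unweighted mean and population-denominator sd of each indicator over the
#' member cities of each group, excluding missing values per indicator
#' (cities without data for an indicator simply drop out of that mean).
#'
#' @param cities Tibble with one row per city (e.g. stacked
#'   [city_percentages()] rows or a published benchmark table).
#' @param group Column name to group by (default `"income_group"`).
#' @return A tibble with `group`, `indicator`, `n`, `mean`, `sd`.
#' @export
group_summary <- function(cities, group = "income_group") {
  stopifnot(group %in% names(cities))
  num_cols <- names(cities)[vapply(cities, is.numeric, logical(1))]
  groups <- unique(cities[[group]])
  groups <- groups[!is.na(groups)]
  rows <- list()
  for (g in c(as.list(groups), list(NULL))) {
    sub <- if (is.null(g)) cities else cities[cities[[group]] %in% g, ]
    label <- if (is.null(g)) "total" else as.character(g)
    if (!nrow(sub)) {
      warning("empty group omitted: ", label)
      next
    }
    for (col in num_cols) {
      v <- sub[[col]]
      v <- v[!is.na(v)]
      if (!length(v)) next
      rows[[length(rows) + 1L]] <- tibble::tibble(
        group = label, indicator = col, n = length(v),
        mean = mean(v), sd = sqrt(mean((v - mean(v))^2))
      )
    }
  }
  dplyr::bind_rows(rows)
}
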