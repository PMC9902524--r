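# Bundled benchmark table: published city-level indicator estimates for 25
# cities in 19 countries (population percentage with 500 m access per
# amenity class, transport-sector PM2.5 emissions, and the percentage of
# population meeting the scenario A/B density thresholds). Used as the
# worked example for the group-summary aggregation and as reference input
# for benchmarking runs; ".." cells in the source are stored as NA.

#' Published 25-city benchmark table
#'
#' City-level population-weighted indicator estimates for 25 cities: access
#' percentages per destination class, transport PM2.5 emissions
#' (tonnes/year), and population percentages meeting the scenario A/B
#' population- and intersection-density thresholds. Missing entries (no
#' retrievable schedule or emissions data) are `NA` and drop out of group
#' means.
#'
#' @return A tibble with one row per city; columns `city`, `country`,
#'   `region`, `income_group`, `pct_access_*`, `pm25_transport`,
#'   `pct_scenario{A,B}_{pop,int}`.
#' @export
city_benchmark_table <- function() {
  path <- system.file("extdata", "city_benchmark.csv", package = "walkshed")
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
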