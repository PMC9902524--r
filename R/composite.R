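# Composite point-level indicators: the daily living score, standardised
# walkability (within-city or between-city reference), and the
# density-threshold scenario flags.

#' Daily living score
#'
#' Count (0-3) of core amenity types within the access threshold: a healthy
#' food market, a convenience store, and any public transport stop. Sums
#' equal-weighted binary access scores.
#'
#' @param access_food,access_convenience,access_pt_any Binary 0/1 vectors.
#' @return Integer vector in 0..3.
#' @export
daily_living_score <- function(access_food, access_convenience,
                               access_pt_any) {
  for (v in list(access_food, access_convenience, access_pt_any)) {
    if (!all(v %in% c(0L, 1L))) {
      stop("daily living inputs must be binary 0/1", call. = FALSE)
    }
  }
  as.integer(access_food + access_convenience + access_pt_any)
}

#' Standardise values against a reference distribution
#'
#' Z-scores `(x - mean) / sd` with the population (n-denominator) standard
#' deviation. The reference defaults to the values themselves (within-city
#' use); pass the pooled all-cities values as `reference` for between-city
#' scores. A zero-variance reference yields all-zero scores with a warning.
#'
#' @param values Numeric vector to standardise.
#' @param reference Numeric vector defining the mean and sd (default
#'   `values`).
#' @return Numeric z-scores, same length as `values`.
#' @export
standardise <- function(values, reference = values) {
  reference <- reference[is.finite(reference)]
  if (length(reference) < 2) {
    stop("reference set needs at least 2 values", call. = FALSE)
  }
  mu <- mean(reference)
  sd_n <- sqrt(mean((reference - mu)^2))
  if (sd_n == 0) {
    warning("zero variance in reference: z-scores set to 0")
    return(rep(0, length(values)))
  }
  (values - mu) / sd_n
}

#' Walkability index
#'
#' Sum of equal-weighted standardised scores of population density, street
#' intersection density and daily living score. All three z-scores must
#' come from the same reference (within-city or between-city); zero means
#' the reference-set average.
#'
#' @param z_pop,z_int,z_daily Z-score vectors from [standardise()] with a
#'   common reference.
#' @return Numeric walkability values.
#' @export
walkability <- function(z_pop, z_int, z_daily) {
  n <- unique(c(length(z_pop), length(z_int), length(z_daily)))
  if (length(n) != 1) {
    stop("z-score inputs have different lengths: mixed references?",
         call. = FALSE)
  }
  z_pop + z_int + z_daily
}

#' Density threshold scenarios
#'
#' Scenario A carries the thresholds associated with an 80% probability of
#' walking for transport; scenario B the (higher) thresholds for at least a
#' 15% relative reduction in insufficient physical activity through
#' walking. Defaults are the lower bounds of the published 95% CIs for each
#' threshold; alternative values can be supplied.
#'
#' @param name `"A"` or `"B"`.
#' @param pop_density_threshold Persons per km2 (defaults: A 4790, B 5677).
#' @param int_density_threshold Intersections per km2 (defaults: A 90,
#'   B 106).
#' @return A `threshold_scenario` list.
#' @export
threshold_scenario <- function(name = c("A", "B"),
                               pop_density_threshold = NULL,
                               int_density_threshold = NULL) {
  name <- match.arg(name)
  defaults <- list(A = c(pop = 4790, int = 90), B = c(pop = 5677, int = 106))
  pop <- pop_density_threshold %||% defaults[[name]][["pop"]]
  int <- int_density_threshold %||% defaults[[name]][["int"]]
  stopifnot(pop > 0, int > 0)
  structure(list(name = name, pop_density_threshold = pop,
                 int_density_threshold = int),
            class = "threshold_scenario")
}

#' Scenario threshold flags
#'
#' A neighbourhood meets a scenario when its density reaches or exceeds the
#' threshold (inclusive).
#'
#' @param pop_density,int_density Numeric density vectors.
#' @param scenario A [threshold_scenario()].
#' @return A tibble with binary `meets_pop` and `meets_int`.
#' @export
scenario_flags <- function(pop_density, int_density, scenario) {
  stopifnot(inherits(scenario, "threshold_scenario"))
  tibble::tibble(
    meets_pop = as.integer(pop_density >= scenario$pop_density_threshold),
    meets_int = as.integer(int_density >= scenario$int_density_threshold)
  )
}
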