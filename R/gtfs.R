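# GTFS schedule analysis: parse a feed, pick a representative weekday, and
# classify stops by average daytime service frequency.
#
# The service-frequency criteria are: any stop; stops with average weekday
# daytime headway of 30 min or less; and of 20 min or less. "Daytime" is
# 07:00-19:00 by default and the representative weekday is the one with the
# most scheduled departures (both configurable: the underlying study
# protocol names neither).

#' Parse a GTFS feed directory
#'
#' Reads the standard comma-separated GTFS text files. Times past 24:00
#' (service running over midnight) are kept on their service day as hours
#' >= 24. Stop coordinates are taken from `stop_lon`/`stop_lat` through
#' `project`, which maps them to the planar analysis CRS; the default
#' identity mapping suits feeds already written in planar metres (such as
#' those from [generate_gtfs()]).
#'
#' @param dir Feed directory containing at least `stops.txt`, `trips.txt`,
#'   `stop_times.txt` and `calendar.txt`.
#' @param project Function `(lon, lat) -> list(x, y)` projecting stop
#'   coordinates to planar metres.
#' @return A `gtfs_feed` object: list of tibbles `stops` (with `x`, `y`),
#'   `routes`, `trips`, `stop_times` (with `departure_s` seconds) and
#'   `calendar`, plus `frequencies` when present.
#' @export
parse_gtfs <- function(dir, project = function(lon, lat) list(x = lon, y = lat)) {
  required <- c("stops.txt", "trips.txt", "stop_times.txt", "calendar.txt")
  missing <- required[!file.exists(file.path(dir, required))]
  if (length(missing)) {
    stop("GTFS feed is missing required file(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  rd <- function(f) {
    tibble::as_tibble(utils::read.csv(file.path(dir, f),
                                      colClasses = "character",
                                      check.names = FALSE))
  }
  stops <- rd("stops.txt")
  trips <- rd("trips.txt")
  stop_times <- rd("stop_times.txt")
  calendar <- rd("calendar.txt")
  xy <- project(as.numeric(stops$stop_lon), as.numeric(stops$stop_lat))
  stops$x <- xy$x
  stops$y <- xy$y
  if (anyDuplicated(stops$stop_id)) stop("duplicate stop_id", call. = FALSE)
  secs <- gtfs_time_to_sec(stop_times$departure_time)
  bad <- is.na(secs) & !is.na(stop_times$departure_time) &
    stop_times$departure_time != ""
  if (any(bad)) {
    warning(sprintf("%d stop_times row(s) with unparseable departure_time dropped",
                    sum(bad)))
  }
  stop_times$departure_s <- secs
  stop_times <- stop_times[!is.na(secs), , drop = FALSE]
  for (col in c("monday", "tuesday", "wednesday", "thursday", "friday",
                "saturday", "sunday")) {
    calendar[[col]] <- as.integer(calendar[[col]])
  }
  feed <- list(stops = stops, trips = trips, stop_times = stop_times,
               calendar = calendar)
  if (file.exists(file.path(dir, "routes.txt"))) feed$routes <- rd("routes.txt")
  if (file.exists(file.path(dir, "frequencies.txt"))) {
    feed$frequencies <- rd("frequencies.txt")
  }
  structure(feed, class = "gtfs_feed")
}

#' Convert "HH:MM:SS" GTFS times to seconds
#'
#' Hours may exceed 24 (trips running past midnight stay on their service
#' day). Unparseable strings map to `NA`.
#'
#' @param x Character vector of GTFS times.
#' @return Numeric seconds since service-day midnight.
#' @export
gtfs_time_to_sec <- function(x) {
  m <- regmatches(x, regexec("^\\s*(\\d+):([0-5]\\d):([0-5]\\d)\\s*$", x))
  vapply(m, function(p) {
    if (length(p) != 4) return(NA_real_)
    as.numeric(p[2]) * 3600 + as.numeric(p[3]) * 60 + as.numeric(p[4])
  }, numeric(1))
}

#' Select the representative weekday services
#'
#' The weekday (Monday-Friday) with the largest total number of scheduled
#' departures is taken as representative; ties go to the earliest day.
#'
#' @param feed A `gtfs_feed`.
#' @return Character vector of active `service_id`s on the chosen weekday
#'   (empty when the feed has no weekday service).
#' @export
representative_weekday <- function(feed) {
  days <- c("monday", "tuesday", "wednesday", "thursday", "friday")
  trip_service <- feed$trips$service_id[match(feed$stop_times$trip_id,
                                              feed$trips$trip_id)]
  totals <- vapply(days, function(d) {
    active <- feed$calendar$service_id[feed$calendar[[d]] == 1]
    sum(trip_service %in% active)
  }, numeric(1))
  if (all(totals == 0)) return(character(0))
  best <- days[which.max(totals)]   # which.max: first index on ties
  feed$calendar$service_id[feed$calendar[[best]] == 1]
}

#' Average daytime headway per stop
#'
#' Departures at each stop from all trips of the active services are pooled
#' inside the daytime window (duplicated `(trip, stop, time)` rows count
#' once), sorted, and the mean of consecutive gaps is the stop's mean
#' headway. Stops with fewer than two windowed departures get an undefined
#' headway and both service classes 0. `frequencies.txt`-based trips are
#' expanded to explicit departures first.
#'
#' @param feed A `gtfs_feed`.
#' @param services Service ids from [representative_weekday()].
#' @param window Daytime window, seconds since midnight
#'   (default 07:00-19:00).
#' @return A tibble `stop_id`, `n_departures`, `mean_headway_min`,
#'   `class_30`, `class_20` covering every stop in the feed.
#' @export
stop_headways <- function(feed, services,
                          window = c(7, 19) * 3600) {
  st <- expand_frequencies(feed)
  trips <- feed$trips[feed$trips$service_id %in% services, ]
  st <- st[st$trip_id %in% trips$trip_id, , drop = FALSE]
  st <- st[st$departure_s >= window[1] & st$departure_s <= window[2], ,
           drop = FALSE]
  st <- dplyr::distinct(st, .data$trip_id, .data$stop_id, .data$departure_s)
  per_stop <- dplyr::summarise(
    dplyr::group_by(st, .data$stop_id),
    n_departures = dplyr::n_distinct(.data$departure_s),
    mean_headway_min = {
      dep <- sort(unique(.data$departure_s))
      if (length(dep) < 2) NA_real_ else mean(diff(dep)) / 60
    },
    .groups = "drop"
  )
  out <- tibble::tibble(stop_id = feed$stops$stop_id)
  out <- dplyr::left_join(out, per_stop, by = "stop_id")
  out$n_departures <- ifelse(is.na(out$n_departures), 0L, out$n_departures)
  out$class_30 <- as.integer(!is.na(out$mean_headway_min) &
                               out$mean_headway_min <= 30)
  out$class_20 <- as.integer(!is.na(out$mean_headway_min) &
                               out$mean_headway_min <= 20)
  out
}

# expand frequencies.txt entries (if any) into explicit stop_times rows
expand_frequencies <- function(feed) {
  st <- feed$stop_times[, c("trip_id", "stop_id", "departure_s")]
  fr <- feed$frequencies
  if (is.null(fr) || !nrow(fr)) return(st)
  freq_trips <- unique(fr$trip_id)
  base <- st[st$trip_id %in% freq_trips, , drop = FALSE]
  rest <- st[!st$trip_id %in% freq_trips, , drop = FALSE]
  out <- list(rest)
  for (i in seq_len(nrow(fr))) {
    tid <- fr$trip_id[i]
    tmpl <- base[base$trip_id == tid, , drop = FALSE]
    if (!nrow(tmpl)) next
    t0 <- min(tmpl$departure_s)
    starts <- seq(gtfs_time_to_sec(fr$start_time[i]),
                  gtfs_time_to_sec(fr$end_time[i]),
                  by = as.numeric(fr$headway_secs[i]))
    for (s in starts) {
      shifted <- tmpl
      shifted$departure_s <- tmpl$departure_s - t0 + s
      out[[length(out) + 1L]] <- shifted
    }
  }
  dplyr::bind_rows(out)
}

#' Build the three public-transport destination layers
#'
#' Stops are snapped to the network and split into `pt_stop_any` (all
#' stops), `pt_stop_30min` and `pt_stop_20min` by their headway class.
#'
#' @param feed A `gtfs_feed`.
#' @param headways Output of [stop_headways()].
#' @param net A `street_network`.
#' @param tolerance Snap tolerance (metres).
#' @return Named list of three snapped `destination_layer`s.
#' @export
transit_stop_layers <- function(feed, headways, net, tolerance = 500) {
  stops <- feed$stops
  stops$dest_id <- seq_len(nrow(stops))
  any_layer <- snap_to_network(
    net, stops[, c("dest_id", "x", "y")], "pt_stop_any", tolerance
  )
  any_layer$stop_id <- stops$stop_id[match(any_layer$dest_id, stops$dest_id)]
  cls <- headways[match(any_layer$stop_id, headways$stop_id), ]
  l30 <- destination_layer(any_layer[cls$class_30 == 1, , drop = FALSE],
                           "pt_stop_30min")
  l20 <- destination_layer(any_layer[cls$class_20 == 1, , drop = FALSE],
                           "pt_stop_20min")
  list(pt_stop_any = any_layer, pt_stop_30min = l30, pt_stop_20min = l20)
}
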