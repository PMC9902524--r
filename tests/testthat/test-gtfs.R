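test_that("GTFS parsing handles after-midnight times and missing files", {
  dir <- write_mini_gtfs(withr::local_tempdir(),
                         departures = c("08:00:00", "25:10:00"))
  feed <- parse_gtfs(dir)
  expect_s3_class(feed$stops, "tbl_df")
  expect_equal(sort(feed$stop_times$departure_s),
               c(8 * 3600, 25 * 3600 + 600))

  expect_equal(gtfs_time_to_sec("25:10:00"), 25 * 3600 + 600)
  expect_true(is.na(gtfs_time_to_sec("8h30")))

  file.remove(file.path(dir, "calendar.txt"))
  expect_error(parse_gtfs(dir), "calendar.txt")
})

test_that("representative weekday maximises departures with earliest-day ties", {
  dir <- write_mini_gtfs(withr::local_tempdir())
  feed <- parse_gtfs(dir)
  expect_equal(representative_weekday(feed), "WD")  # Mon-Fri tie -> Monday

  # a second service running only Wednesday with more departures wins
  dir2 <- withr::local_tempdir()
  write_mini_gtfs(dir2)
  trips <- utils::read.csv(file.path(dir2, "trips.txt"))
  extra_trips <- data.frame(route_id = "R1", service_id = "WED",
                            trip_id = paste0("W", 1:9))
  utils::write.csv(rbind(trips, extra_trips), file.path(dir2, "trips.txt"),
                   row.names = FALSE, quote = FALSE)
  st <- utils::read.csv(file.path(dir2, "stop_times.txt"))
  extra_st <- data.frame(trip_id = paste0("W", 1:9),
                         arrival_time = sprintf("09:%02d:00", 1:9),
                         departure_time = sprintf("09:%02d:00", 1:9),
                         stop_id = "S1", stop_sequence = 1)
  utils::write.csv(rbind(st, extra_st), file.path(dir2, "stop_times.txt"),
                   row.names = FALSE, quote = FALSE)
  cal <- utils::read.csv(file.path(dir2, "calendar.txt"))
  cal2 <- rbind(cal, data.frame(service_id = "WED", monday = 0, tuesday = 0,
                                wednesday = 1, thursday = 0, friday = 0,
                                saturday = 0, sunday = 0,
                                start_date = "20150105",
                                end_date = "20151231"))
  utils::write.csv(cal2, file.path(dir2, "calendar.txt"),
                   row.names = FALSE, quote = FALSE)
  feed2 <- parse_gtfs(dir2)
  # Wednesday wins; both services running that day are returned
  expect_setequal(representative_weekday(feed2), c("WD", "WED"))

  # weekend-only feed has no representative weekday
  dir3 <- write_mini_gtfs(withr::local_tempdir(),
                          weekdays = c(0, 0, 0, 0, 0))
  expect_length(representative_weekday(parse_gtfs(dir3)), 0)
})

test_that("stop headways average consecutive gaps in the daytime window", {
  dir <- write_mini_gtfs(withr::local_tempdir(),
                         departures = c("08:00:00", "08:20:00", "08:40:00"))
  feed <- parse_gtfs(dir)
  hw <- stop_headways(feed, representative_weekday(feed))
  expect_equal(hw$mean_headway_min, 20)
  expect_equal(hw$class_30, 1L)
  expect_equal(hw$class_20, 1L)

  single <- write_mini_gtfs(withr::local_tempdir(),
                            departures = "09:00:00")
  hws <- stop_headways(parse_gtfs(single),
                       representative_weekday(parse_gtfs(single)))
  expect_true(is.na(hws$mean_headway_min))
  expect_equal(hws$class_30, 0L)
  expect_equal(hws$class_20, 0L)

  # departures outside 07:00-19:00 are ignored
  night <- write_mini_gtfs(withr::local_tempdir(),
                           departures = c("05:00:00", "08:00:00",
                                          "08:30:00", "23:00:00"))
  hwn <- stop_headways(parse_gtfs(night),
                       representative_weekday(parse_gtfs(night)))
  expect_equal(hwn$n_departures, 2)
  expect_equal(hwn$mean_headway_min, 30)
  expect_equal(hwn$class_30, 1L)
  expect_equal(hwn$class_20, 0L)
})

test_that("mean headway is invariant under schedule duplication", {
  dir <- write_mini_gtfs(withr::local_tempdir(),
                         departures = c("08:00:00", "08:25:00", "08:50:00"))
  feed <- parse_gtfs(dir)
  base <- stop_headways(feed, representative_weekday(feed))

  # duplicate the whole schedule under a different route
  trips <- utils::read.csv(file.path(dir, "trips.txt"))
  dup <- trips
  dup$route_id <- "R2"
  dup$trip_id <- paste0("D", seq_len(nrow(dup)))
  utils::write.csv(rbind(trips, dup), file.path(dir, "trips.txt"),
                   row.names = FALSE, quote = FALSE)
  st <- utils::read.csv(file.path(dir, "stop_times.txt"))
  dst <- st
  dst$trip_id <- paste0("D", match(dst$trip_id, trips$trip_id))
  utils::write.csv(rbind(st, dst), file.path(dir, "stop_times.txt"),
                   row.names = FALSE, quote = FALSE)
  feed2 <- parse_gtfs(dir)
  dupd <- stop_headways(feed2, representative_weekday(feed2))
  expect_equal(dupd$mean_headway_min, base$mean_headway_min)
})

test_that("synthetic feeds round-trip their headway", {
  spec <- city_spec(seed = 4, transit_headway_min = 25, n_stops = 3)
  city <- generate_city(spec)
  dir <- withr::local_tempdir()
  generate_gtfs(spec, city$destinations$pt_stop, dir)

  # 16 h window at 25 min: seq(6h, 22h, 25min) departures per stop
  st <- utils::read.csv(file.path(dir, "stop_times.txt"))
  expect_equal(nrow(st) / 3, length(seq(6 * 3600, 22 * 3600, 25 * 60)))
  cal <- utils::read.csv(file.path(dir, "calendar.txt"))
  expect_equal(cal$saturday + cal$sunday, 0)

  feed <- parse_gtfs(dir)
  expect_equal(nrow(feed$stops), 3)
  hw <- stop_headways(feed, representative_weekday(feed))
  expect_equal(hw$mean_headway_min, rep(25, 3), tolerance = 1e-9)
  expect_equal(hw$class_30, rep(1L, 3))
  expect_equal(hw$class_20, rep(0L, 3))

  # halving the headway halves the measured mean
  spec10 <- city_spec(seed = 4, transit_headway_min = 12.5, n_stops = 3)
  dir2 <- withr::local_tempdir()
  generate_gtfs(spec10, city$destinations$pt_stop, dir2)
  feed2 <- parse_gtfs(dir2)
  hw2 <- stop_headways(feed2, representative_weekday(feed2))
  expect_equal(hw2$mean_headway_min, hw$mean_headway_min / 2,
               tolerance = 1e-9)
})

test_that("20 min headway feeds produce 49 departures per stop", {
  spec <- city_spec(seed = 5, transit_headway_min = 20, n_stops = 2)
  city <- generate_city(spec)
  dir <- withr::local_tempdir()
  generate_gtfs(spec, city$destinations$pt_stop, dir)
  st <- utils::read.csv(file.path(dir, "stop_times.txt"))
  expect_equal(as.integer(table(st$stop_id)), c(49L, 49L))
})

test_that("frequency-based trips are expanded before pooling", {
  dir <- write_mini_gtfs(withr::local_tempdir(), departures = "08:00:00")
  utils::write.csv(
    data.frame(trip_id = "T1", start_time = "08:00:00",
               end_time = "10:00:00", headway_secs = 1800),
    file.path(dir, "frequencies.txt"), row.names = FALSE, quote = FALSE
  )
  feed <- parse_gtfs(dir)
  hw <- stop_headways(feed, representative_weekday(feed))
  expect_equal(hw$n_departures, 5)       # 08:00..10:00 every 30 min
  expect_equal(hw$mean_headway_min, 30)
})
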