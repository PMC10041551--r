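# Telemetry ingestion, projection, thinning, seasons, habitat, QC.

test_that("read_telemetry parses, projects and reports bad rows", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("animal_id,species,timestamp,lon,lat",
               "A1,red,2017-06-01T12:00:00,-94.0,58.0",
               "A1,red,2017-06-02T12:00:00,-94.0,59.0",
               "A1,red,2017-06-03T12:00:00,-94.1,58.5",
               "A1,red,2017-06-04T12:00:00,-94.0,"), f)
  tr <- read_telemetry(f, center = c(-94, 58.5))
  expect_length(tr, 1)
  expect_equal(nrow(tr$A1), 3)
  expect_equal(nrow(attr(tr, "rejected")), 1)
  expect_match(attr(tr, "rejected")$reason, "coordinate")
  # two points 1 degree apart in latitude at the projection origin:
  # geodesic distance ~111.2 km on the authalic sphere
  d <- sqrt(sum((as.numeric(tr$A1[2, c("x", "y")]) -
                 as.numeric(tr$A1[1, c("x", "y")]))^2))
  expect_equal(d, 111.2, tolerance = 0.005)
  # planar input passes through unchanged
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("animal_id,species,timestamp,x_km,y_km",
               "B1,arctic,2017-06-01T12:00:00,3.5,-2.25"), f2)
  tr2 <- read_telemetry(f2)
  expect_equal(tr2$B1$x, 3.5)
  expect_equal(tr2$B1$y, -2.25)
  # missing columns error
  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("animal_id,timestamp,lon,lat", "A,2017-06-01,0,0"), f3)
  expect_error(read_telemetry(f3), "missing required column")
})

test_that("telemetry round-trips through the CSV dialect", {
  tr <- straight_track(5)
  f <- withr::local_tempfile(fileext = ".csv")
  write_telemetry(tr, f)
  back <- read_telemetry(f)
  expect_equal(back$S1$x, tr$x)
  expect_equal(back$S1$y, tr$y)
  expect_equal(back$S1$timestamp, tr$timestamp)
})

test_that("daily thinning keeps one uniform fix per day, deterministically", {
  ts <- as.POSIXct("2017-06-01 00:30:00", tz = "UTC") +
    seq(0, by = 3600, length.out = 48)          # 48 hourly fixes, 2 UTC-6 days
  tr <- foxmove:::new_track(data.frame(
    animal_id = "A", species = "red", timestamp = ts,
    x = seq_along(ts), y = 0, stringsAsFactors = FALSE))
  th <- thin_daily(tr, seed = 5, day_offset_hours = 0)
  expect_equal(nrow(th), 2)
  expect_true(foxmove:::is_thinned(th))
  expect_identical(thin_daily(tr, seed = 5, day_offset_hours = 0), th)
  # idempotence
  expect_equal(thin_daily(th, seed = 123, day_offset_hours = 0)$timestamp,
               th$timestamp)
  # single-fix day always kept
  one <- foxmove:::new_track(tr[10, , drop = FALSE])
  expect_equal(thin_daily(one, seed = 1)$timestamp, tr$timestamp[10])
  # gapless daily track: mean inter-fix interval exactly 24 h
  daily <- straight_track(30)
  expect_equal(mean(diff(as.numeric(daily$timestamp))) / 3600, 24)
  expect_error(thin_daily(tr[0, ], seed = 1), "empty")
})

test_that("thinning selection frequencies are uniform across fixes", {
  # one day with 10 fixes; 1000 master seeds; each fix should be chosen
  # with frequency 0.1 within the binomial 99% bound
  ts <- as.POSIXct("2017-06-01 01:00:00", tz = "UTC") +
    seq(0, by = 3600, length.out = 10)
  tr <- foxmove:::new_track(data.frame(
    animal_id = "A", species = "red", timestamp = ts,
    x = 1:10, y = 0, stringsAsFactors = FALSE))
  picks <- vapply(0:999, function(s)
    thin_daily(tr, seed = s, day_offset_hours = 0)$x, numeric(1))
  freq <- tabulate(picks, 10) / 1000
  bound <- 2.576 * sqrt(0.1 * 0.9 / 1000)
  expect_true(all(abs(freq - 0.1) <= bound))
})

test_that("season windows partition the year with the documented edges", {
  d <- function(x) as.POSIXct(paste0("2018-", x, " 12:00:00"), tz = "UTC")
  expect_equal(assign_season(d("05-14")), "winter")
  expect_equal(assign_season(d("05-15")), "summer")
  expect_equal(assign_season(d("10-31")), "summer")
  expect_equal(assign_season(d("11-01")), "winter")
  # total and single-valued across a whole year
  days <- seq(as.POSIXct("2018-01-01 12:00:00", tz = "UTC"),
              by = "1 day", length.out = 365)
  lab <- assign_season(days)
  expect_false(anyNA(lab))
  expect_setequal(unique(lab), c("summer", "winter"))
  # wrapping winter belongs to its starting year
  expect_equal(season_instance(d("01-15")), "winter-2017")
  expect_equal(season_instance(d("11-02")), "winter-2018")
  expect_equal(season_instance(d("06-01")), "summer-2018")
})

test_that("habitat classification uses land-priority tie-break and ice flag", {
  w <- demo_world()
  jan <- as.POSIXct("2018-01-15 12:00:00", tz = "UTC")
  aug <- as.POSIXct("2018-08-15 12:00:00", tz = "UTC")
  lab <- classify_habitat(c(0, 0, 0, 0, 9999), c(0, 100, -200, 50, 0), w,
                          rep(jan, 5))
  expect_equal(as.character(lab), c("land", "sea", "forest", "land",
                                    "unknown"))
  expect_false(any(attr(lab, "implausible")))
  # sea point outside the ice window is flagged
  lab2 <- classify_habitat(0, 100, w, aug)
  expect_equal(as.character(lab2), "sea")
  expect_true(attr(lab2, "implausible"))
})

test_that("speed filter removes only double-implausible fixes", {
  # hour-spaced fixes so a 500 km teleport implies absurd speeds
  ts <- as.POSIXct("2017-06-01 00:00:00", tz = "UTC") + (0:9) * 3600
  tr <- foxmove:::new_track(data.frame(
    animal_id = "A", species = "red", timestamp = ts,
    x = 0, y = seq(0, 9), stringsAsFactors = FALSE))
  expect_equal(nrow(qc_speed_filter(tr, 50)), 10)
  tp <- tr
  tp$x[5] <- 500
  tp <- foxmove:::new_track(tp)
  out <- qc_speed_filter(tp, 50)
  expect_equal(nrow(out), 9)
  expect_equal(attr(out, "rejected")$x, 500)
  # infinite threshold is the identity
  expect_equal(nrow(qc_speed_filter(tp, Inf)), 10)
})
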