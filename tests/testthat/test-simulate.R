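# Synthetic trajectory generator.

test_that("resident simulation is deterministic and respects rate zero", {
  w <- demo_world()
  p <- resident_params("red", excursion_rate = 0, commuting_rate = 0)
  t1 <- simulate_resident(w, p, n_days = 120, seed = 1)
  expect_equal(nrow(attr(t1, "truth")), 0)
  t7a <- simulate_resident(w, p, n_days = 120, seed = 7)
  t7b <- simulate_resident(w, p, n_days = 120, seed = 7)
  expect_identical(t7a, t7b)
  expect_false(identical(t1$x, t7a$x))
  # one fix per day at noon
  expect_equal(unique(format(t7a$timestamp, "%H:%M")), "12:00")
  expect_equal(unique(diff(as.numeric(t7a$timestamp))), 86400)
  expect_error(simulate_resident(w, p, n_days = 30, seed = 1), "60")
  expect_error(simulate_resident(w, resident_params("red",
    centroid = c(0, 2000)), n_days = 120, seed = 1), "land")
})

test_that("all fixes stay on mapped habitat; sea only inside ice window", {
  w <- demo_world()
  co <- simulate_cohort(list(n_red = 2, n_arctic = 3,
                             n_arctic_dispersers = 1, n_days = 400,
                             resident_daily_hazard = 0), seed = 3)
  for (tr in co$tracks) {
    expect_false(any(tr$habitat == "unknown"))
    sea <- tr$habitat == "sea"
    if (any(sea)) {
      doy <- as.POSIXlt(tr$timestamp[sea], tz = "UTC")$yday + 1L
      expect_true(all(foxmove:::in_ice_window(doy, w)))
    }
  }
})

test_that("planted excursions obey the operational definition", {
  w <- demo_world()
  p <- resident_params("arctic", excursion_rate = c(summer = 0.3,
                                                    winter = 0.3),
                       commuting_rate = 0.3, excursion_max_days = 3)
  tr <- simulate_resident(w, p, n_days = 365, seed = 11)
  tru <- attr(tr, "truth")
  expect_gt(nrow(tru), 0)
  dur <- as.numeric(difftime(tru$end_ts, tru$start_ts, units = "days")) + 1
  expect_true(all(dur < 7))
  # bracketed by in-range days: events never touch the track ends
  expect_true(all(tru$start_ts > min(tr$timestamp)))
  expect_true(all(tru$end_ts < max(tr$timestamp)))
  # commuting bouts reach the sea
  com <- tru[tru$event_type == "commuting", ]
  expect_gt(nrow(com), 0)
  for (i in seq_len(nrow(com))) {
    ix <- tr$timestamp >= com$start_ts[i] & tr$timestamp <= com$end_ts[i]
    expect_true(any(tr$habitat[ix] == "sea"))
  }
})

test_that("straight disperser gives exactly CSLD 1 and bearing 0", {
  w <- demo_world()
  dp <- disperser_params("red", start_doy = 330, bearing_deg = 0,
                         target_distance = 100, daily_speed = 10,
                         tortuosity = 1, substrate = "land",
                         settle_days = NA)
  tr <- simulate_disperser(w, dp, resident_prefix_days = 0, seed = 1)
  ev <- segment_dispersal(tr, NULL, tactic_settings())
  expect_equal(ev$duration_days, 10)
  expect_equal(ev$cumulative_km, 100)
  expect_equal(ev$csld_ratio, 1.0)
  expect_equal(ev$bearing_deg, 0)
  expect_equal(ev$mean_daily_speed, 10)
  # ice dispersal outside the ice window errors
  expect_error(simulate_disperser(w,
    disperser_params("arctic", start_doy = 250), seed = 1),
    "ice window")
})

test_that("red-like dispersals recover the planted cumulative distance", {
  # planted truth: straight-line target x tortuosity = 200.80 km mean
  w <- demo_world()
  cums <- vapply(1:20, function(s) {
    dp <- disperser_params("red")
    tr <- simulate_disperser(w, dp, resident_prefix_days = 0, seed = s)
    ev <- segment_dispersal(tr, NULL, tactic_settings())
    ev$cumulative_km
  }, numeric(1))
  se <- stats::sd(cums) / sqrt(length(cums))
  expect_lt(abs(mean(cums) - 200.80), 2 * se)
})

test_that("settlement is localized relative to the dispersal path", {
  w <- demo_world()
  dp <- disperser_params("red", settle_days = 10)
  tr <- simulate_disperser(w, dp, resident_prefix_days = 0, seed = 9)
  tru <- attr(tr, "truth")
  expect_equal(tru$end_reason, "settled")
  n <- nrow(tr)
  tail10 <- cbind(tr$x, tr$y)[(n - 9):n, ]
  ud <- estimate_ud(tail10, levels = 1.0)
  path <- cbind(tr$x, tr$y)[seq_len(n - 10), ]
  bbox <- prod(apply(apply(path, 2, range), 2, diff))
  expect_lt(ud_area(ud, 1.0), 0.1 * bbox)
})

test_that("cohorts carry coherent ground truth", {
  co <- simulate_cohort(list(n_red = 10, n_arctic = 0, n_days = 120,
                             resident_daily_hazard = 0), seed = 2)
  expect_equal(nrow(co$truth), 10)
  expect_true(all(co$truth$tactic == "resident"))
  co2 <- simulate_cohort(list(n_red = 5, n_arctic = 5,
                              n_red_dispersers = 5, n_arctic_dispersers = 5,
                              resident_daily_hazard = 0), seed = 4)
  expect_true(all(co2$truth$substrate[co2$truth$species == "red"] == "land"))
  expect_true(all(co2$truth$substrate[co2$truth$species == "arctic"] == "ice"))
  expect_error(simulate_cohort(list(n_red = 0, n_arctic = 0), seed = 1),
               "at least one")
  # determinism of the whole cohort
  co3 <- simulate_cohort(list(n_red = 2, n_arctic = 2,
                              n_arctic_dispersers = 1), seed = 6)
  co4 <- simulate_cohort(list(n_red = 2, n_arctic = 2,
                              n_arctic_dispersers = 1), seed = 6)
  expect_identical(co3$tracks, co4$tracks)
})

test_that("planted dispersal fraction is recovered over a large cohort", {
  co <- simulate_cohort(list(n_red = 50, n_arctic = 50, p_disperse = 0.56,
                             n_days = 120, resident_daily_hazard = 0),
                        seed = 10)
  frac <- mean(co$truth$tactic == "disperser")
  # binomial 99% interval around 0.56 at n = 100 (a fixed-seed draw;
  # the 99% bound keeps the check meaningful without being brittle)
  expect_lt(abs(frac - 0.56), 2.576 * sqrt(0.56 * 0.44 / 100))
})
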