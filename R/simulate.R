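# Synthetic telemetry generator.
#
# Residents follow a discrete-daily Ornstein-Uhlenbeck walk around a
# fixed activity centre, with the stationary spread calibrated so the
# downstream a-LoCoH 95% isopleth area matches a season-specific target.
# Dispersers follow a directed walk with wrapped-normal heading noise
# whose spread is set analytically from the target straightness ratio.
# Only one fix per day (at noon UTC) is emitted: downstream analysis is
# daily, so sub-daily realism would be dead weight.

# Ratio of the a-LoCoH 95% isopleth area (a = max pairwise distance) to
# the stationary bivariate-normal 95% ellipse area
# pi * qchisq(.95, 2) * sd^2, as a function of the number of daily
# fixes: the hull union of a finite sample undershoots the ellipse, less
# so at larger n. Frozen from a 24-replicate-per-point Monte-Carlo
# calibration of OU tracks at reversion 1/day (see methods vignette);
# interpolated linearly in log n, clamped outside the calibrated range.
ALOCOH_CAL_N <- c(60, 100, 140, 180, 240, 300)
ALOCOH_CAL_C <- 0.97 * c(0.349, 0.440, 0.524, 0.588, 0.644, 0.667)

alocoh_factor <- function(n_fixes) {
  stats::approx(log(ALOCOH_CAL_N), ALOCOH_CAL_C, xout = log(n_fixes),
                rule = 2)$y
}

CHI2_95_2D <- stats::qchisq(0.95, df = 2)

# Per-axis stationary sd whose n-fix a-LoCoH 95% isopleth has the target
# area in expectation.
area_to_sd <- function(area_km2, n_fixes = 180) {
  sqrt(area_km2 / (pi * CHI2_95_2D * alocoh_factor(n_fixes)))
}

#' Resident movement parameters
#'
#' Defaults follow the seasonal home-range contrast of a low-Arctic fox
#' system: summer ranges near 16-18 km^2 in both species, winter ranges
#' expanding to ~35 km^2 in red foxes but staying ~20 km^2 in Arctic
#' foxes; weekly excursion rates of order 0.05-0.25; sea-ice commuting
#' for Arctic-like animals only.
#'
#' @param species "red" or "arctic"; sets area and rate defaults.
#' @param centroid activity centre (km).
#' @param summer_hr_area,winter_hr_area target 95% isopleth areas (km^2).
#' @param ou_reversion mean-reversion rate (1/day) of the
#'   Ornstein-Uhlenbeck kernel.
#' @param excursion_rate expected land excursions per week; length 1 or
#'   a named c(summer=, winter=) pair.
#' @param excursion_max_days longest planted excursion (must stay < 7).
#' @param commuting_rate expected sea-ice commuting trips per week
#'   (realised only inside the ice window).
#' @return object of class `resident_params`.
#' @export
resident_params <- function(species = c("red", "arctic"),
                            centroid = c(0, 0),
                            summer_hr_area = NULL, winter_hr_area = NULL,
                            ou_reversion = 1.0,
                            excursion_rate = NULL,
                            excursion_max_days = 3L,
                            commuting_rate = NULL) {
  species <- match.arg(species)
  if (is.null(summer_hr_area)) {
    summer_hr_area <- if (species == "red") 18.06 else 15.86
  }
  if (is.null(winter_hr_area)) {
    winter_hr_area <- if (species == "red") 34.72 else 19.81
  }
  if (is.null(excursion_rate)) {
    excursion_rate <- if (species == "red") c(summer = 0.05, winter = 0.13)
                      else c(summer = 0.08, winter = 0.06)
  }
  if (length(excursion_rate) == 1 && is.null(names(excursion_rate))) {
    excursion_rate <- c(summer = unname(excursion_rate),
                        winter = unname(excursion_rate))
  }
  if (is.null(commuting_rate)) {
    commuting_rate <- if (species == "arctic") 0.15 else 0
  }
  stopifnot(summer_hr_area > 0, winter_hr_area > 0,
            all(excursion_rate >= 0), commuting_rate >= 0,
            excursion_max_days >= 1, excursion_max_days < 7,
            ou_reversion > 0)
  structure(list(species = species, centroid = centroid,
                 summer_hr_area = summer_hr_area,
                 winter_hr_area = winter_hr_area,
                 ou_reversion = ou_reversion,
                 excursion_rate = excursion_rate,
                 excursion_max_days = as.integer(excursion_max_days),
                 commuting_rate = commuting_rate),
            class = "resident_params")
}

#' Disperser movement parameters
#'
#' Defaults echo the contrast between a short, straight, land-bound
#' red-fox-like dispersal (cumulative distance ~200 km over ~15 days,
#' straightness ratio ~1.5, ~15 km/day) and a long, tortuous,
#' ice-borne Arctic-fox-like one (~1243 km over ~43 days, ratio ~4.4,
#' ~28 km/day). `target_distance` is the straight-line displacement at
#' which the animal stops dispersing, so the expected cumulative
#' distance is `target_distance * tortuosity`.
#'
#' @param species "red" or "arctic"; sets defaults.
#' @param start_doy day-of-year dispersal starts.
#' @param bearing_deg mean heading, degrees clockwise from due North.
#' @param target_distance straight-line displacement goal (km).
#' @param daily_speed mean step length (km/day).
#' @param tortuosity target cumulative / straight-line ratio (>= 1).
#' @param substrate "land", "ice" or "mixed"; "ice" requires the start
#'   day to fall inside the ice window.
#' @param settle_days days of localized settlement after the dispersal,
#'   or NA for death at dispersal end.
#' @return object of class `disperser_params`.
#' @export
disperser_params <- function(species = c("red", "arctic"),
                             start_doy = NULL, bearing_deg = NULL,
                             target_distance = NULL, daily_speed = NULL,
                             tortuosity = NULL, substrate = NULL,
                             settle_days = 10L) {
  species <- match.arg(species)
  if (is.null(start_doy)) {
    # winter departures; ice-borne ones must wait for ice consolidation
    start_doy <- if (species == "red") 330L else 345L
  }
  if (is.null(bearing_deg)) bearing_deg <- if (species == "red") 225 else 0
  if (is.null(tortuosity)) tortuosity <- if (species == "red") 1.50 else 4.36
  if (is.null(daily_speed)) daily_speed <- if (species == "red") 15.24 else 27.96
  if (is.null(target_distance)) {
    target_distance <- if (species == "red") 200.80 / 1.50 else 1243.00 / 4.36
  }
  if (is.null(substrate)) substrate <- if (species == "red") "land" else "ice"
  stopifnot(target_distance > 0, tortuosity >= 1, daily_speed > 0,
            substrate %in% c("land", "ice", "mixed"))
  structure(list(species = species, start_doy = as.integer(start_doy),
                 bearing_deg = bearing_deg %% 360,
                 target_distance = target_distance,
                 daily_speed = daily_speed, tortuosity = tortuosity,
                 substrate = substrate, settle_days = settle_days),
            class = "disperser_params")
}

noon_seq <- function(start_date, n_days) {
  as.POSIXct(paste(as.Date(start_date), "12:00:00"), tz = "UTC") +
    (seq_len(n_days) - 1) * 86400
}

world_clamp_land <- function(xy, world) {
  lx <- range(world$land[, 1]); ly <- range(world$land[, 2])
  c(min(max(xy[1], lx[1] + 1), lx[2] - 1),
    min(max(xy[2], ly[1] + 1), ly[2] - 1))
}

#' Simulate a resident track
#'
#' Daily Ornstein-Uhlenbeck positions around `params$centroid`, the
#' stationary spread switching with season so the downstream 95%
#' isopleth area tracks the seasonal target. Planted excursion bouts
#' leave the range out-and-back to at least 3x the stationary range
#' radius in under 7 days; commuting bouts do the same onto the sea
#' polygon, only inside the ice window. All planted events are recorded
#' as ground truth.
#'
#' @param world a `fox_world`.
#' @param params a [resident_params()] bundle.
#' @param start_date first day (Date or string).
#' @param n_days track length (>= 60).
#' @param seed integer seed; same seed, same track.
#' @param animal_id id carried into the track.
#' @return a thinned `fox_track` with attribute `truth` (data.frame of
#'   planted events: event_type, start_ts, end_ts, apex_km).
#' @export
simulate_resident <- function(world, params, start_date = "2017-05-15",
                              n_days = 365L, seed = 1L,
                              animal_id = "R1") {
  if (n_days < 60) stop("n_days must be >= 60")
  if (!pip(params$centroid[1], params$centroid[2], world$land)) {
    stop("resident centroid must lie inside the land polygon")
  }
  ts <- noon_seq(start_date, n_days)
  season <- assign_season(ts)
  doy <- as.POSIXlt(ts, tz = "UTC")$yday + 1L
  phi <- exp(-params$ou_reversion)
  # spread calibrated per season instance: the UD is estimated per
  # animal-season downstream, so each instance's fix count sets its factor
  inst <- season_instance(ts)
  n_inst <- stats::ave(seq_along(inst), inst, FUN = length)
  sd_day <- ifelse(season == "summer",
                   area_to_sd(params$summer_hr_area, n_inst),
                   area_to_sd(params$winter_hr_area, n_inst))
  mu <- params$centroid
  withr::with_seed(as.integer(seed %% 2147483647), {
    xy <- matrix(NA_real_, n_days, 2)
    pos <- mu + stats::rnorm(2, 0, sd_day[1])
    bout_left <- 0L; bout_path <- NULL
    truth <- list()
    for (t in seq_len(n_days)) {
      if (bout_left > 0L) {
        xy[t, ] <- bout_path[nrow(bout_path) - bout_left + 1L, ]
        bout_left <- bout_left - 1L
        next
      }
      step_sd <- sd_day[t] * sqrt(1 - phi^2)
      pos <- mu + phi * (pos - mu) + stats::rnorm(2, 0, step_sd)
      pos <- world_clamp_land(pos, world)
      xy[t, ] <- pos
      if (t >= n_days - 1L) next       # keep the final fix in-range
      rate <- unname(params$excursion_rate[season[t]])
      commute_ok <- params$commuting_rate > 0 && in_ice_window(doy[t], world)
      p_exc <- rate / 7
      p_com <- if (commute_ok) params$commuting_rate / 7 else 0
      u <- stats::runif(1)
      kind <- if (u < p_exc) "excursion"
              else if (u < p_exc + p_com) "commuting" else NA
      if (is.na(kind)) next
      d <- sample.int(params$excursion_max_days, 1)
      d <- min(d, n_days - t - 1L)     # leave room for the return fix
      if (d < 1L) next
      R <- sqrt(CHI2_95_2D) * sd_day[t]
      apex_dist <- (3 + stats::runif(1)) * R
      if (kind == "commuting") {
        brg <- (stats::runif(1, -20, 20)) * pi / 180          # due north-ish
        coast_gap <- min(world$sea[, 2]) - mu[2]
        apex_dist <- max(apex_dist,
                         (coast_gap + 3 + 2 * stats::runif(1)) / cos(brg))
      } else {
        brg <- stats::runif(1, 100, 260) * pi / 180           # landward arc
      }
      apex <- mu + apex_dist * c(sin(brg), cos(brg))
      if (kind == "excursion") apex <- world_clamp_land(apex, world)
      # triangular out-and-back profile that always touches the apex
      k <- seq_len(d)
      frac <- pmin(k, d + 1 - k) / ceiling(d / 2)
      bout_path <- cbind(pos[1] + frac * (apex[1] - pos[1]),
                         pos[2] + frac * (apex[2] - pos[2]))
      truth[[length(truth) + 1L]] <- data.frame(
        animal_id = animal_id, event_type = kind,
        start_ts = ts[t + 1L], end_ts = ts[t + d],
        apex_km = sqrt(sum((apex - mu)^2)))
      bout_left <- d
    }
  })
  habitat <- classify_habitat(xy[, 1], xy[, 2], world, ts)
  tr <- new_track(data.frame(animal_id = animal_id,
                             species = params$species,
                             timestamp = ts, x = xy[, 1], y = xy[, 2],
                             habitat = as.character(habitat),
                             stringsAsFactors = FALSE), thinned = TRUE)
  attr(tr, "truth") <- if (length(truth)) do.call(rbind, truth) else
    data.frame(animal_id = character(0), event_type = character(0),
               start_ts = as.POSIXct(character(0), tz = "UTC"),
               end_ts = as.POSIXct(character(0), tz = "UTC"),
               apex_km = numeric(0))
  tr
}

#' Simulate a dispersing track
#'
#' Optional resident prefix (OU around the land centroid), then a
#' directed walk: daily heading = bearing + N(0, s^2) with
#' s = sqrt(2 log tortuosity), so the expected straightness ratio of the
#' walk equals `tortuosity` (headings of a straight walk, s = 0, give
#' ratio exactly 1). The walk stops once the straight-line displacement
#' from the departure fix reaches `target_distance`, then either settles
#' (localized fixes on land for `settle_days` days) or ends in death.
#'
#' @param world a `fox_world`.
#' @param params a [disperser_params()] bundle.
#' @param resident_prefix_days days of residency before departure (>= 0).
#' @param seed integer seed.
#' @param year calendar year containing `start_doy`.
#' @param animal_id id carried into the track.
#' @param home resident centroid (km) for the prefix and departure.
#' @return a thinned `fox_track` with attribute `truth`: a one-row
#'   data.frame (event_type "dispersal", start/end fix indices and
#'   timestamps, end_reason, death_date).
#' @export
simulate_disperser <- function(world, params, resident_prefix_days = 30L,
                               seed = 1L, year = 2017L,
                               animal_id = "D1", home = c(0, 0)) {
  if (resident_prefix_days < 0) stop("resident_prefix_days must be >= 0")
  if (params$substrate == "ice" &&
      !in_ice_window(params$start_doy, world)) {
    stop("substrate 'ice' requested but start_doy ", params$start_doy,
         " is outside the ice window")
  }
  start_disp <- as.Date(params$start_doy - 1L,
                        origin = as.Date(paste0(year, "-01-01")))
  settle_days <- params$settle_days
  dies <- is.na(settle_days) || settle_days <= 0
  s_head <- sqrt(2 * log(params$tortuosity))
  withr::with_seed(as.integer(seed %% 2147483647), {
    # resident prefix
    if (resident_prefix_days > 0) {
      pre <- simulate_resident(world,
        resident_params(params$species, centroid = home,
                        excursion_rate = 0, commuting_rate = 0),
        start_date = start_disp - resident_prefix_days,
        n_days = max(60L, resident_prefix_days), seed = seed,
        animal_id = animal_id)
      pre <- pre[seq_len(resident_prefix_days), , drop = FALSE]
      pos <- c(pre$x[nrow(pre)], pre$y[nrow(pre)])
    } else {
      # no prior residency: the track still starts at the point of capture
      pre <- data.frame(x = home[1], y = home[2])
      pos <- home
    }
    dep <- pos                          # departure fix = last in-range fix
    brg0 <- params$bearing_deg * pi / 180
    path <- list()
    max_steps <- ceiling(6 * params$target_distance / params$daily_speed) + 60L
    repeat {
      delta <- if (s_head > 0) stats::rnorm(1, 0, s_head) else 0
      brg <- brg0 + delta
      pos <- pos + params$daily_speed * c(sin(brg), cos(brg))
      pos[1] <- min(max(pos[1], -2990), 2990)
      pos[2] <- min(max(pos[2], -2990), 2990)
      path[[length(path) + 1L]] <- pos
      if (sqrt(sum((pos - dep)^2)) >= params$target_distance) break
      if (length(path) >= max_steps) break
    }
    walk <- do.call(rbind, path)
    if (!dies) {
      center <- walk[nrow(walk), ]
      ly <- range(world$land[, 2])
      if (center[2] > ly[2]) center[2] <- ly[2] - 10   # came ashore
      if (center[2] < ly[1]) center[2] <- ly[1] + 10
      settle <- cbind(center[1] + stats::rnorm(settle_days, 0, 0.5),
                      center[2] + stats::rnorm(settle_days, 0, 0.5))
    } else {
      settle <- NULL
    }
  })
  xy <- rbind(if (!is.null(pre)) cbind(pre$x, pre$y), walk, settle)
  n <- nrow(xy)
  ts <- noon_seq(start_disp - resident_prefix_days, n)
  habitat <- classify_habitat(xy[, 1], xy[, 2], world, ts)
  tr <- new_track(data.frame(animal_id = animal_id,
                             species = params$species,
                             timestamp = ts, x = xy[, 1], y = xy[, 2],
                             habitat = as.character(habitat),
                             stringsAsFactors = FALSE), thinned = TRUE)
  n_pre <- max(1L, resident_prefix_days)   # capture fix counts when no prefix
  start_idx <- n_pre
  end_idx <- min(n_pre + nrow(walk) + if (dies) 0L else 1L, n)
  attr(tr, "truth") <- data.frame(
    animal_id = animal_id, event_type = "dispersal",
    start_idx = start_idx, end_idx = end_idx,
    start_ts = ts[start_idx], end_ts = ts[end_idx],
    end_reason = if (dies) "died" else "settled",
    death_date = if (dies) as.Date(ts[n]) else as.Date(NA),
    substrate = params$substrate)
  tr
}

#' Simulate a mixed cohort with ground truth
#'
#' Assembles residents and winter dispersers of both species, applies
#' tactic-dependent exponential mortality from November 1 (default
#' disperser/resident hazard ratio 9), and returns tracks plus a
#' ground-truth label table suitable as a full-pipeline fixture.
#'
#' @param spec a list: `n_red`, `n_arctic` (animal counts, required,
#'   total >= 1); either `p_disperse` (per-animal winter dispersal
#'   probability) or explicit `n_red_dispersers` / `n_arctic_dispersers`;
#'   optional `start_date` (default "2017-05-15"), `n_days` (default
#'   320), `resident_daily_hazard` (default 5e-4), `hazard_ratio`
#'   (default 9), `dispersal_doy_range` (default c(318, 130): mid
#'   November to early May, wrapping).
#' @param seed master seed; every animal draws from an id-derived
#'   substream.
#' @param world a `fox_world`.
#' @return list: `tracks` (named list of `fox_track`), `truth`
#'   (data.frame: animal_id, species, tactic, substrate, death_date),
#'   `events` (row-bound per-track ground-truth events).
#' @export
simulate_cohort <- function(spec, seed = 1L, world = default_world()) {
  n_red <- spec$n_red %||% 0L
  n_arctic <- spec$n_arctic %||% 0L
  if (n_red + n_arctic < 1) stop("cohort must contain at least one animal")
  start_date <- as.Date(spec$start_date %||% "2017-05-15")
  n_days <- spec$n_days %||% 320L
  h_res <- spec$resident_daily_hazard %||% 5e-4
  hr <- spec$hazard_ratio %||% 9
  doy_rng <- spec$dispersal_doy_range %||% c(318L, 130L)
  ids <- c(if (n_red) paste0("RF", seq_len(n_red)),
           if (n_arctic) paste0("AF", seq_len(n_arctic)))
  species <- c(rep("red", n_red), rep("arctic", n_arctic))
  n <- length(ids)
  tactic <- withr::with_seed(as.integer(seed %% 2147483647), {
    if (!is.null(spec$p_disperse)) {
      ifelse(stats::runif(n) < spec$p_disperse, "disperser", "resident")
    } else {
      t0 <- rep("resident", n)
      nd_r <- spec$n_red_dispersers %||% 0L
      nd_a <- spec$n_arctic_dispersers %||% 0L
      if (nd_r > n_red || nd_a > n_arctic) stop("more dispersers than animals")
      if (nd_r) t0[seq_len(nd_r)] <- "disperser"
      if (nd_a) t0[n_red + seq_len(nd_a)] <- "disperser"
      t0
    }
  })
  year <- as.integer(format(start_date, "%Y"))
  tracks <- vector("list", n); names(tracks) <- ids
  truth <- vector("list", n); events <- list()
  for (i in seq_len(n)) {
    sd_i <- animal_seed(seed, ids[i])
    home <- withr::with_seed(sd_i, c(stats::runif(1, -40, 40),
                                     stats::runif(1, -30, 20)))
    # tactic-specific winter mortality: exponential survival from the
    # first November 1 of the track, hazard h_res (resident) or
    # h_res * hazard_ratio (disperser); the tactic's hazard applies over
    # the whole winter at risk, so a fixed-covariate Cox fit on the
    # exported table targets the planted ratio directly
    if (tactic[i] == "resident") {
      tr <- simulate_resident(world, resident_params(species[i],
                                                     centroid = home),
                              start_date = start_date, n_days = n_days,
                              seed = sd_i, animal_id = ids[i])
      hz <- h_res
      nov1 <- as.Date(paste0(year, "-11-01"))
    } else {
      dd <- withr::with_seed(seed_off(sd_i, 2), {
        lo <- doy_rng[1]; hi <- doy_rng[2]
        allowed <- if (lo <= hi) lo:hi else c(lo:365L, 1L:hi)
        if (species[i] == "arctic") {      # ice dispersal needs the platform
          allowed <- allowed[in_ice_window(allowed, world)]
        }
        allowed[sample.int(length(allowed), 1)]
      })
      dp <- disperser_params(species[i], start_doy = dd, settle_days = 12L)
      yr <- if (dd < 182L) year + 1L else year      # spring starts: next year
      tr <- simulate_disperser(world, dp, resident_prefix_days = 90L,
                               seed = sd_i, year = yr,
                               animal_id = ids[i], home = home)
      hz <- h_res * hr
      nov1 <- as.Date(paste0(if (dd < 182L) year else yr, "-11-01"))
    }
    death <- if (hz > 0) withr::with_seed(seed_off(sd_i, 1), {
      d <- nov1 + ceiling(stats::rexp(1, rate = hz))
      first_day <- as.Date(tr$timestamp[1])
      if (d < first_day + 10) d <- first_day + 10    # never an empty track
      if (d <= as.Date(tr$timestamp[nrow(tr)])) d else as.Date(NA)
    }) else as.Date(NA)
    ev <- attr(tr, "truth")
    if (!is.na(death)) {
      tr <- new_track(tr[as.Date(tr$timestamp) <= death, , drop = FALSE],
                      thinned = TRUE)
      if (tactic[i] == "disperser") {
        if (nrow(tr) < ev$end_idx) {           # died before settling
          ev$end_idx <- nrow(tr)
          ev$end_ts <- tr$timestamp[nrow(tr)]
          ev$end_reason <- "died"
        }
        ev$death_date <- death
        ev <- ev[ev$start_idx < nrow(tr), , drop = FALSE]  # never departed
      } else {
        ev <- ev[ev$end_ts <= max(tr$timestamp), , drop = FALSE]
      }
      attr(tr, "truth") <- ev
    }
    truth[[i]] <- data.frame(animal_id = ids[i], species = species[i],
                             tactic = tactic[i],
                             substrate = if (tactic[i] == "disperser")
                               dp$substrate else NA_character_,
                             death_date = death)
    tracks[[i]] <- tr
    if (!is.null(ev) && nrow(ev)) events[[length(events) + 1L]] <- ev
  }
  list(tracks = tracks, truth = do.call(rbind, truth),
       events = events)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Derive a related seed without risking integer overflow.
seed_off <- function(s, k) as.integer((as.numeric(s) + k) %% 2147483629)

#' Write ground-truth events as a sidecar CSV
#'
#' @param cohort result of [simulate_cohort()].
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_truth <- function(cohort, path) {
  lab <- cohort$truth
  lab$death_date <- as.character(lab$death_date)
  utils::write.csv(lab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
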