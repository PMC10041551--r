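# Movement-tactic classification and dispersal segmentation.
#
# An animal-season is resident when it keeps a circumscribed range
# (nondirectional movement) through the whole season; it is a disperser
# when a sustained directional departure from the prior range is
# segmented. The season of capture is excluded from tactic comparisons
# because residency before capture is unobservable.

#' Dispersal segmentation and residency settings
#'
#' The published rules leave two quantities open, which are stated here
#' explicitly: a departure counts as dispersal initiation only when the
#' terminal out-of-range run lasts at least `min_departure_days` and
#' ends at least `min_dispersal_km` from the prior range centroid; a
#' "new delimited ranging area" is a window of more than 7 days (>= 8
#' calendar days, at most one gap day) whose land fixes stay within
#' `r_settle` km of their own centroid.
#'
#' @param min_fixes minimum fixes for residency assessment (default 38,
#'   the average range-area asymptote).
#' @param min_departure_days minimum length of the departing run (days).
#' @param min_dispersal_km minimum net displacement from the prior range
#'   centroid for a departure to count as dispersal.
#' @param r_settle settlement disc radius (km).
#' @param settle_min_days settlement window length in days (> 7).
#' @param max_gap_days gap days tolerated inside the settlement window.
#' @return a list of settings.
#' @export
tactic_settings <- function(min_fixes = 38L, min_departure_days = 3L,
                            min_dispersal_km = 10, r_settle = 5,
                            settle_min_days = 8L, max_gap_days = 1L) {
  list(min_fixes = as.integer(min_fixes),
       min_departure_days = as.integer(min_departure_days),
       min_dispersal_km = min_dispersal_km, r_settle = r_settle,
       settle_min_days = as.integer(settle_min_days),
       max_gap_days = as.integer(max_gap_days))
}

track_xy <- function(track) cbind(track$x, track$y)

substrate_of <- function(habitat) {
  ifelse(habitat == "sea", "ice",
         ifelse(habitat %in% c("land", "forest"), "land", NA_character_))
}

# Majority substrate with a 70% dominance rule; otherwise "mixed".
main_substrate <- function(habitat) {
  s <- substrate_of(habitat)
  s <- s[!is.na(s)]
  if (!length(s)) return(NA_character_)
  f_land <- mean(s == "land")
  if (f_land >= 0.7) "land" else if (f_land <= 0.3) "ice" else "mixed"
}

bearing_from_north <- function(dx, dy) (atan2(dx, dy) * 180 / pi) %% 360

dispersal_metrics <- function(track, start_idx, end_idx, end_reason) {
  seg <- track[start_idx:end_idx, , drop = FALSE]
  xy <- track_xy(seg)
  steps <- sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2)
  cumulative <- sum(steps)
  straight <- sqrt(sum((xy[nrow(xy), ] - xy[1, ])^2))
  duration <- as.numeric(difftime(seg$timestamp[nrow(seg)],
                                  seg$timestamp[1], units = "days"))
  list(animal_id = track$animal_id[1], species = track$species[1],
       start_idx = start_idx, end_idx = end_idx,
       start_ts = seg$timestamp[1], end_ts = seg$timestamp[nrow(seg)],
       end_reason = end_reason,
       duration_days = duration,
       cumulative_km = cumulative,
       straight_km = straight,
       csld_ratio = if (straight > 0) cumulative / straight else Inf,
       bearing_deg = bearing_from_north(xy[nrow(xy), 1] - xy[1, 1],
                                        xy[nrow(xy), 2] - xy[1, 2]),
       mean_daily_speed = if (duration > 0) cumulative / duration else NA_real_,
       main_substrate = if ("habitat" %in% names(seg))
         main_substrate(seg$habitat[-1]) else NA_character_)
}

# First fix index of the earliest settlement window: a run of fixes
# spanning >= settle_min_days with <= max_gap_days missing days, all on
# land, all within r_settle of the window centroid.
find_settlement <- function(track, from_idx, cfg) {
  n <- nrow(track)
  if (from_idx > n) return(NA_integer_)
  day <- as.numeric(as.Date(track$timestamp))
  land <- if ("habitat" %in% names(track)) {
    substrate_of(track$habitat) %in% "land"
  } else rep(TRUE, n)
  for (i in from_idx:n) {
    if (!land[i]) next
    j <- i
    while (j < n && land[j + 1L] &&
           day[j + 1L] - day[j] <= cfg$max_gap_days + 1) {
      j <- j + 1L
      if (day[j] - day[i] + 1 >= cfg$settle_min_days) break
    }
    if (day[j] - day[i] + 1 < cfg$settle_min_days) next
    w <- i:j
    ctr <- c(mean(track$x[w]), mean(track$y[w]))
    if (max(sqrt((track$x[w] - ctr[1])^2 + (track$y[w] - ctr[2])^2)) <=
        cfg$r_settle) return(i)
  }
  NA_integer_
}

#' Segment a dispersal event from a thinned track
#'
#' The event starts at the last fix inside the prior 95% isopleth before
#' the track leaves it for good (or at the first fix when no prior range
#' exists, as for an animal collared while already dispersing) and ends
#' at the first fix of the earliest settlement window on land, or at the
#' last fix (reason "died" when a death date is supplied, else
#' "track_end"). Departures shorter than `min_departure_days` or ending
#' closer than `min_dispersal_km` to the prior range centroid are not
#' dispersals.
#'
#' @param track a thinned `fox_track`.
#' @param prior_ud `fox_ud` of the animal's prior range, or NULL.
#' @param settings a [tactic_settings()] list.
#' @param death_date optional Date of death (end-reason bookkeeping).
#' @return a one-row data.frame of class `dispersal_event`, or NULL when
#'   no dispersal is segmented.
#' @export
segment_dispersal <- function(track, prior_ud = NULL,
                              settings = tactic_settings(),
                              death_date = NULL) {
  n <- nrow(track)
  if (n < 2) return(NULL)
  xy <- track_xy(track)
  if (!is.null(prior_ud)) {
    inside <- ud_contains(prior_ud, xy, 0.95)
    if (all(inside)) return(NULL)
    last_in <- max(c(0L, which(inside)))
    if (last_in == n) return(NULL)              # ends at home: no dispersal
    start_idx <- max(1L, last_in)
    ref <- prior_ud$centroid
  } else {
    start_idx <- 1L
    ref <- xy[1, ]
  }
  run_days <- as.numeric(difftime(track$timestamp[n],
                                  track$timestamp[start_idx],
                                  units = "days"))
  if (run_days < settings$min_departure_days) return(NULL)
  settle_idx <- find_settlement(track, start_idx + 1L, settings)
  end_idx <- if (!is.na(settle_idx)) settle_idx else n
  if (sqrt(sum((xy[end_idx, ] - ref)^2)) < settings$min_dispersal_km) {
    return(NULL)
  }
  end_reason <- if (!is.na(settle_idx)) "settled"
                else if (!is.null(death_date) && !is.na(death_date)) "died"
                else "track_end"
  ev <- dispersal_metrics(track, start_idx, end_idx, end_reason)
  out <- as.data.frame(ev, stringsAsFactors = FALSE)
  class(out) <- c("dispersal_event", "data.frame")
  out
}

#' Classify the movement tactic of one animal-season
#'
#' Resident: enough fixes, no dispersal segmented, and nondirectional
#' movement (net displacement between the centroids of the two track
#' halves smaller than the 95% range diameter). Disperser: a dispersal
#' event is segmented. Otherwise "insufficient". The prior range used
#' for segmentation is estimated from the first `min_fixes` fixes of the
#' season; if that prefix already fails residency (halves displaced),
#' the animal is treated as collared while dispersing (no prior range).
#'
#' @param track a thinned `fox_track`, already restricted to one season
#'   instance.
#' @param season label carried into the result.
#' @param settings a [tactic_settings()] list.
#' @param death_date optional Date of death.
#' @param prior_ud optional `fox_ud` of the animal's known prior range
#'   (e.g. from the preceding resident season); when NULL it is
#'   estimated from the first `min_fixes` fixes of this season.
#' @return list: `tactic` ("resident", "disperser" or "insufficient"),
#'   `event` (the `dispersal_event` or NULL), `ud` (the prior-range
#'   `fox_ud` or NULL).
#' @export
classify_tactic <- function(track, season = NA_character_,
                            settings = tactic_settings(),
                            death_date = NULL, prior_ud = NULL) {
  n <- nrow(track)
  if (n < settings$min_fixes) {
    return(list(tactic = "insufficient", season = season, event = NULL,
                ud = NULL))
  }
  xy <- track_xy(track)
  if (is.null(prior_ud)) {
    prefix <- seq_len(settings$min_fixes)
    pre_xy <- xy[prefix, , drop = FALSE]
    h1 <- pre_xy[seq_len(floor(length(prefix) / 2)), , drop = FALSE]
    h2 <- pre_xy[-seq_len(floor(length(prefix) / 2)), , drop = FALSE]
    pre_shift <- sqrt(sum((colMeans(h2) - colMeans(h1))^2))
    pre_diam <- max(stats::dist(pre_xy))
    if (pre_shift < 0.5 * pre_diam) {
      prior_ud <- tryCatch(estimate_ud(pre_xy, levels = c(0.50, 0.95),
                                       animal_id = track$animal_id[1],
                                       season = season),
                           error = function(e) NULL)
    }
  }
  ev <- segment_dispersal(track, prior_ud, settings, death_date)
  if (!is.null(ev)) {
    return(list(tactic = "disperser", season = season, event = ev,
                ud = prior_ud))
  }
  # nondirectional check over the whole season
  half <- floor(n / 2)
  shift <- sqrt(sum((colMeans(xy[(half + 1):n, , drop = FALSE]) -
                     colMeans(xy[seq_len(half), , drop = FALSE]))^2))
  ud <- tryCatch(estimate_ud(xy, levels = c(0.50, 0.95),
                             animal_id = track$animal_id[1],
                             season = season),
                 error = function(e) NULL)
  diam <- if (!is.null(ud)) {
    hulls_diameter(ud$isopleths[[ud_level_index(ud, 0.95)]])
  } else max(stats::dist(xy))
  if (shift >= diam) {
    return(list(tactic = "insufficient", season = season, event = NULL,
                ud = ud))
  }
  list(tactic = "resident", season = season, event = NULL, ud = ud)
}

#' Summarise dispersal metrics per species
#'
#' Mean, SE, median, min, max and n for duration, cumulative distance,
#' straightness ratio and daily speed, one block per species — the shape
#' of a standard dispersal-parameter table.
#'
#' @param events data.frame of row-bound `dispersal_event`s.
#' @return data.frame with columns species, parameter, mean, se, median,
#'   min, max, n. SE is NA for single events.
#' @export
dispersal_summary <- function(events) {
  if (is.null(events) || nrow(events) == 0) stop("no dispersal events")
  pars <- c(duration_days = "Duration", cumulative_km = "Distance",
            csld_ratio = "CSLD ratio", mean_daily_speed = "Speed")
  out <- list()
  for (sp in unique(events$species)) {
    e <- events[events$species == sp, , drop = FALSE]
    for (p in names(pars)) {
      v <- e[[p]]
      out[[length(out) + 1L]] <- data.frame(
        species = sp, parameter = pars[[p]],
        mean = mean(v),
        se = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_,
        median = stats::median(v), min = min(v), max = max(v),
        n = length(v))
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Build a right-censored winter survival table
#'
#' Time-to-event is the number of days since the start of the winter
#' (November 1). Deaths inside the window contribute events; animals
#' surviving past the window end (May 14) are censored there; animals
#' whose tracking ends earlier are censored at their last fix.
#'
#' @param labels data.frame with columns animal_id, winter_year (the
#'   calendar year containing the November 1 that starts the winter),
#'   tactic, death_date (Date or NA) and optionally last_obs (Date).
#' @return data.frame: animal_id, winter_year, tactic, time_days, event
#'   (1 = death, 0 = censored).
#' @export
build_survival_table <- function(labels) {
  stopifnot(all(c("animal_id", "winter_year", "tactic", "death_date")
                %in% names(labels)))
  out <- lapply(seq_len(nrow(labels)), function(i) {
    nov1 <- as.Date(paste0(labels$winter_year[i], "-11-01"))
    wend <- as.Date(paste0(labels$winter_year[i] + 1L, "-05-14"))
    dd <- labels$death_date[i]
    lo <- if ("last_obs" %in% names(labels) && !is.na(labels$last_obs[i])) {
      labels$last_obs[i]
    } else wend
    if (!is.na(dd) && dd <= wend) {
      if (dd < nov1) stop("death before the start of its winter: ",
                          labels$animal_id[i])
      t <- as.numeric(dd - nov1); e <- 1L
    } else {
      t <- as.numeric(min(wend, lo) - nov1); e <- 0L
    }
    data.frame(animal_id = labels$animal_id[i],
               winter_year = labels$winter_year[i],
               tactic = labels$tactic[i], time_days = t, event = e)
  })
  do.call(rbind, out)
}
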