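# End-to-end pipeline: simulate or ingest -> thin -> per-season tactic
# classification -> home ranges -> excursions -> summary tables, with a
# run manifest for byte-identical reruns.

#' Demo pipeline configuration
#'
#' A small simulated cohort (6 residents, 4 dispersers across the two
#' species) that exercises every stage in a few minutes on one CPU.
#'
#' @param seed master seed.
#' @return a config list accepted by [run_pipeline()].
#' @export
demo_config <- function(seed = 42L) {
  list(seed = as.integer(seed),
       simulate = list(n_red = 4L, n_arctic = 6L,
                       n_red_dispersers = 2L, n_arctic_dispersers = 2L,
                       start_date = "2017-05-15", n_days = 500L),
       thin = list(day_offset_hours = -6),
       qc = list(max_kmh = NULL),
       tactics = list(min_fixes = 38L),
       excursions = list(k = 3, transform = "auto"),
       exclude_capture_season = TRUE)
}

num_fmt <- function(x) formatC(x, digits = 10, format = "g")

write_table <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1)) & !vapply(df, is.integer, logical(1))
  for (cn in names(df)[num]) df[[cn]] <- num_fmt(df[[cn]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or CSV ingest) -> thin -> per-animal-season tactic
#' classification -> dispersal metrics -> resident home ranges and
#' seasonal shifts -> excursion detection -> summary tables and
#' permutation tests, writing every intermediate table plus a manifest
#' to `outdir`. Rerunning with the same config and seed reproduces the
#' tables byte-identically.
#'
#' @param config a config list (see [demo_config()]) or path to a YAML
#'   file with the same structure. Either a `simulate` block or a
#'   `telemetry` path must be present.
#' @param outdir output directory, created if needed.
#' @return invisibly, a list with the main tables (labels, events,
#'   hr_areas, hr_summary, shifts, excursions, frequencies, survival,
#'   tests) and `files` (paths written).
#' @export
run_pipeline <- function(config, outdir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$seed)) stop("config must set a seed")
  seed <- as.integer(config$seed)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  world <- default_world()
  tset <- do.call(tactic_settings,
                  config$tactics %||% list())

  # --- stage: simulate or ingest -------------------------------------
  truth <- NULL
  if (!is.null(config$simulate)) {
    cohort <- simulate_cohort(config$simulate, seed = seed, world = world)
    tracks <- cohort$tracks
    truth <- cohort$truth
    files <- c(files, write_telemetry(tracks, file.path(outdir, "telemetry.csv")))
    files <- c(files, write_truth(cohort, file.path(outdir, "ground_truth.csv")))
    files <- c(files, write_world_geojson(world, file.path(outdir, "world.geojson")))
  } else if (!is.null(config$telemetry)) {
    tracks <- read_telemetry(config$telemetry)
  } else {
    stop("config needs a 'simulate' block or a 'telemetry' path")
  }
  if (!length(tracks)) stop("no animals in input")

  # --- stage: thin + optional QC -------------------------------------
  off <- (config$thin %||% list())$day_offset_hours %||% -6
  tracks <- lapply(tracks, thin_daily, seed = seed, day_offset_hours = off)
  maxk <- (config$qc %||% list())$max_kmh
  if (!is.null(maxk)) tracks <- lapply(tracks, qc_speed_filter, max_kmh = maxk)
  for (id in names(tracks)) {
    t <- tracks[[id]]
    if (!("habitat" %in% names(t))) {
      t$habitat <- as.character(classify_habitat(t$x, t$y, world, t$timestamp))
      tracks[[id]] <- new_track(t, thinned = TRUE)
    }
  }

  # --- stage: tactics, home ranges, excursions per animal-season -----
  labels <- list(); events <- list(); hr_rows <- list()
  shifts <- list(); exc_rows <- list(); freq_rows <- list()
  uds <- list()
  for (id in names(tracks)) {
    tr <- tracks[[id]]
    inst <- season_instance(tr$timestamp)
    death <- if (!is.null(truth)) truth$death_date[truth$animal_id == id][1]
             else as.Date(NA)
    prior <- NULL
    insts <- unique(inst)               # chronological: track is time-sorted
    for (k in seq_along(insts)) {
      si <- insts[k]
      sub <- new_track(tr[inst == si, , drop = FALSE], thinned = TRUE)
      cls <- classify_tactic(sub, season = si, settings = tset,
                             death_date = death, prior_ud = prior)
      excluded <- isTRUE(config$exclude_capture_season %||% TRUE) && k == 1L
      labels[[length(labels) + 1L]] <- data.frame(
        animal_id = id, species = sub$species[1], season = si,
        n_fixes = nrow(sub), tactic = cls$tactic,
        excluded_capture_season = excluded)
      if (cls$tactic == "disperser") {
        ev <- cls$event
        ev$season <- si
        ev$capture_season <- excluded
        events[[length(events) + 1L]] <- ev
        prior <- NULL
      } else if (cls$tactic == "resident" && !is.null(cls$ud)) {
        exc <- analyze_excursions(sub, cls$ud,
                                  k = (config$excursions %||% list())$k %||% 3,
                                  transform = (config$excursions %||%
                                                 list())$transform %||% "auto")
        ud <- exc$ud              # range refit without far-outlier fixes
        uds[[paste(id, si)]] <- ud
        hr_rows[[length(hr_rows) + 1L]] <- data.frame(
          animal_id = id, species = sub$species[1], season = si,
          season_label = sub("-.*$", "", si), n_fixes = nrow(sub),
          area50_km2 = ud_area(ud, 0.50), area95_km2 = ud_area(ud, 0.95),
          excluded_capture_season = excluded)
        if (nrow(exc$events)) {
          exc$events$season <- si
          exc_rows[[length(exc_rows) + 1L]] <- exc$events
        }
        f <- exc$freq
        f$season <- si
        f$season_label <- sub("-.*$", "", si)
        f$species <- sub$species[1]
        freq_rows[[length(freq_rows) + 1L]] <- f
        prior <- ud
      } else {
        prior <- NULL
      }
    }
  }
  labels <- do.call(rbind, labels)
  events <- if (length(events)) do.call(rbind, events) else NULL
  hr <- if (length(hr_rows)) do.call(rbind, hr_rows) else NULL

  # seasonal shifts: consecutive resident summer/winter UDs per animal
  for (id in unique(labels$animal_id)) {
    mine <- names(uds)[startsWith(names(uds), paste0(id, " "))]
    if (length(mine) < 2) next
    for (k in seq_len(length(mine) - 1L)) {
      s <- seasonal_shift(uds[[mine[k]]], uds[[mine[k + 1L]]])
      s$animal_id <- id
      s$from <- sub("^\\S+ ", "", mine[k])
      s$to <- sub("^\\S+ ", "", mine[k + 1L])
      shifts[[length(shifts) + 1L]] <- s
    }
  }
  shifts <- if (length(shifts)) do.call(rbind, shifts) else NULL

  # --- stage: summaries, survival, tests -----------------------------
  hr_summary <- NULL
  if (!is.null(hr)) {
    use <- hr[!hr$excluded_capture_season, , drop = FALSE]
    if (nrow(use)) {
      hr_summary <- do.call(rbind, lapply(split(use,
          list(use$season_label, use$species), drop = TRUE), function(g) {
        do.call(rbind, lapply(c(95, 50), function(lv) {
          v <- if (lv == 95) g$area95_km2 else g$area50_km2
          data.frame(season = g$season_label[1], species = g$species[1],
                     ud_level = lv, mean = mean(v),
                     se = if (length(v) > 1) stats::sd(v) / sqrt(length(v))
                          else NA_real_,
                     min = min(v), max = max(v), n = length(v))
        }))
      }))
      rownames(hr_summary) <- NULL
    }
  }
  survival <- NULL
  if (any(grepl("^winter", labels$season))) {
    # dispersal events count even in the capture season (tactic and
    # range comparisons exclude it, survival does not)
    wl <- labels[grepl("^winter", labels$season) &
                 (labels$tactic == "disperser" |
                  (labels$tactic == "resident" &
                   !labels$excluded_capture_season)), , drop = FALSE]
    if (nrow(wl)) {
      wl$winter_year <- as.integer(sub("^winter-", "", wl$season))
      wl$death_date <- as.Date(NA)
      wl$last_obs <- as.Date(NA)
      for (i in seq_len(nrow(wl))) {
        tr <- tracks[[wl$animal_id[i]]]
        wl$last_obs[i] <- as.Date(max(tr$timestamp))
        if (!is.null(truth)) {
          wl$death_date[i] <-
            truth$death_date[truth$animal_id == wl$animal_id[i]][1]
        }
      }
      survival <- build_survival_table(wl)
    }
  }
  tests <- NULL
  if (!is.null(events)) {
    by_sp <- split(events, events$species)
    if (length(by_sp) == 2 && all(vapply(by_sp, nrow, integer(1)) >= 2)) {
      tests <- do.call(rbind, lapply(
        c("duration_days", "cumulative_km", "csld_ratio",
          "mean_daily_speed"), function(p) {
          pt <- permutation_t_test(by_sp[[1]][[p]], by_sp[[2]][[p]],
                                   n_perm = 9999L, seed = seed)
          data.frame(parameter = p, group_a = names(by_sp)[1],
                     group_b = names(by_sp)[2], t = pt$t_observed,
                     p = pt$p_two_sided, exact = pt$exact,
                     alpha = 0.1)
        }))
    }
  }

  # --- write outputs -------------------------------------------------
  files <- c(files, write_table(labels, file.path(outdir, "tactic_labels.csv")))
  if (!is.null(events)) {
    ev <- events
    ev$start_ts <- format(ev$start_ts, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
    ev$end_ts <- format(ev$end_ts, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
    files <- c(files, write_table(ev, file.path(outdir, "dispersal_events.csv")))
    files <- c(files, write_table(dispersal_summary(events),
                                  file.path(outdir, "dispersal_summary.csv")))
  }
  if (!is.null(hr)) {
    files <- c(files, write_table(hr, file.path(outdir, "homerange_areas.csv")))
  }
  if (!is.null(hr_summary)) {
    files <- c(files, write_table(hr_summary,
                                  file.path(outdir, "homerange_summary.csv")))
  }
  if (!is.null(shifts)) {
    files <- c(files, write_table(shifts, file.path(outdir, "seasonal_shifts.csv")))
  }
  if (length(exc_rows)) {
    ex <- do.call(rbind, exc_rows)
    ex$start_ts <- format(ex$start_ts, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
    ex$end_ts <- format(ex$end_ts, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
    files <- c(files, write_table(ex, file.path(outdir, "excursions.csv")))
  }
  if (length(freq_rows)) {
    files <- c(files, write_table(do.call(rbind, freq_rows),
                                  file.path(outdir, "excursion_frequency.csv")))
  }
  if (!is.null(survival)) {
    files <- c(files, write_table(survival, file.path(outdir, "survival.csv")))
  }
  if (!is.null(tests)) {
    files <- c(files, write_table(tests, file.path(outdir, "permutation_tests.csv")))
  }
  for (nm in names(uds)) {
    fn <- file.path(outdir, paste0("ud_", gsub("[^A-Za-z0-9_-]", "_", nm),
                                   ".geojson"))
    files <- c(files, write_ud_geojson(uds[[nm]], fn))
  }
  manifest <- list(package = "foxmove",
                   version = as.character(utils::packageVersion("foxmove")),
                   seed = seed, config = config,
                   files = sort(basename(files)))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = 10)
  invisible(list(labels = labels, events = events, hr_areas = hr,
                 hr_summary = hr_summary, shifts = shifts,
                 excursions = if (length(exc_rows)) do.call(rbind, exc_rows)
                              else NULL,
                 frequencies = if (length(freq_rows))
                   do.call(rbind, freq_rows) else NULL,
                 survival = survival, tests = tests, uds = uds,
                 tracks = tracks, truth = truth,
                 files = c(files, file.path(outdir, "manifest.json"))))
}
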