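# Extraterritorial excursion detection for residents.
#
# A trip is a maximal run of consecutive fixes outside the 95% isopleth,
# bracketed by in-range fixes (a run that hits the end of the track never
# returned, so it is not an excursion candidate). A trip is an excursion
# when its farthest fix is an outlier of the animal-season distribution
# of distances to the home-range centroid, judged by a one-sided Hampel
# filter (upper bound = median + k * MAD on a Tukey
# ladder-of-powers-transformed scale), and it lasts under 7 days.
# An excursion whose fixes touch the sea ice is a commuting trip.

TUKEY_LADDER <- c(-1, -0.5, 0, 1/3, 0.5, 1)

tukey_apply <- function(x, lambda) {
  if (lambda == 0) log(x)
  else if (lambda < 0) -(x^lambda)        # sign kept monotone increasing
  else x^lambda
}

tukey_invert <- function(y, lambda) {
  if (lambda == 0) return(exp(y))
  if (lambda < 0) {
    # t(x) = -x^lambda maps (0, Inf) onto (-Inf, 0); a bound at or above
    # 0 is beyond the transform's range, i.e. no finite raw threshold
    if (y >= 0) return(Inf)
    return((-y)^(1 / lambda))
  }
  if (y < 0) return(0)
  y^(1 / lambda)
}

# Pick the ladder exponent maximizing normal-quantile correlation of the
# transformed sample. The correlation is computed on the lower 95% so
# that the very outliers the filter is meant to catch cannot drive the
# choice of transform (strong negative exponents "normalise" a
# contaminated tail by crushing it). Exponents needing positive data are
# skipped when zeros are present.
tukey_select <- function(x) {
  cand <- TUKEY_LADDER
  if (any(x <= 0)) cand <- cand[cand > 0]
  if (!length(cand)) return(1)
  sx <- sort(x)
  n_use <- max(5L, floor(0.95 * length(sx)))
  sx <- sx[seq_len(n_use)]
  q <- stats::qnorm(stats::ppoints(length(x)))[seq_len(n_use)]
  score <- vapply(cand, function(l) {
    tx <- tukey_apply(sx, l)
    if (any(!is.finite(tx)) || stats::sd(tx) == 0) return(-Inf)
    stats::cor(tx, q)
  }, numeric(1))
  cand[which.max(score)]
}

#' Distances from fixes to the home-range centroid
#'
#' @param track a `fox_track` (one animal-season).
#' @param ud the animal-season `fox_ud`; its 95%-isopleth centroid is
#'   the center of activity.
#' @return numeric vector of Euclidean distances (km), one per fix.
#' @export
centroid_distances <- function(track, ud) {
  if (is.null(ud)) stop("a resident utilization distribution is required")
  ctr <- ud$centroid
  sqrt((track$x - ctr[1])^2 + (track$y - ctr[2])^2)
}

#' One-sided Hampel outlier bound on transformed distances
#'
#' Applies a Tukey ladder-of-powers transform (exponent chosen by
#' normal-quantile correlation unless pinned), computes
#' median + k * MAD on the transformed scale, and returns the raw-scale
#' threshold through the inverse transform. The MAD is unscaled by
#' default (the rule is "3 median absolute deviations", not 3 robust
#' SDs); set `mad_constant = 1.4826` for the consistency-scaled variant.
#'
#' @param distances numeric vector (>= 5 values).
#' @param k multiplier (default 3).
#' @param transform "auto" (ladder selection), "log", "identity", or a
#'   numeric ladder exponent.
#' @param mad_constant scale factor for the MAD (default 1).
#' @return list of class `hampel_bound`: lambda, median, mad, k,
#'   bound_transformed, bound_km (raw scale).
#' @export
hampel_bound <- function(distances, k = 3, transform = "auto",
                         mad_constant = 1) {
  if (length(distances) < 5) stop("need at least 5 distances")
  lambda <- if (identical(transform, "auto")) tukey_select(distances)
            else if (identical(transform, "log")) 0
            else if (identical(transform, "identity")) 1
            else as.numeric(transform)
  if (lambda <= 0 && any(distances <= 0)) lambda <- 1   # log/neg undefined at 0
  tx <- tukey_apply(distances, lambda)
  med <- stats::median(tx)
  md <- stats::median(abs(tx - med)) * mad_constant
  bt <- med + k * md
  structure(list(lambda = lambda, median = med, mad = md, k = k,
                 bound_transformed = bt,
                 bound_km = tukey_invert(bt, lambda)),
            class = "hampel_bound")
}

#' Detect out-of-range trips
#'
#' Maximal runs of consecutive fixes outside the 95% isopleth bracketed
#' by in-range fixes. Runs still open at the end of the track are
#' dropped (no return observed). The farthest fix of each trip carries
#' its distance to the range centroid.
#'
#' @param track a `fox_track` (one animal-season).
#' @param ud the animal-season `fox_ud`.
#' @return data.frame, one row per trip: start_idx, end_idx, start_ts,
#'   end_ts, duration_days, n_fixes, farthest_idx, farthest_km,
#'   on_sea (any trip fix with sea habitat).
#' @export
detect_trips <- function(track, ud) {
  xy <- track_xy(track)
  inside <- ud_contains(ud, xy, 0.95)
  d <- centroid_distances(track, ud)
  r <- rle(!inside)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- list()
  for (g in which(r$values)) {
    if (starts[g] == 1L || ends[g] == nrow(track)) next  # not bracketed
    ix <- starts[g]:ends[g]
    far <- ix[which.max(d[ix])]
    # duration: days away from range, bracketing fixes one day out each side
    dur <- as.numeric(difftime(track$timestamp[ends[g]],
                               track$timestamp[starts[g]],
                               units = "days")) + 1
    out[[length(out) + 1L]] <- data.frame(
      start_idx = starts[g], end_idx = ends[g],
      start_ts = track$timestamp[starts[g]],
      end_ts = track$timestamp[ends[g]],
      duration_days = dur, n_fixes = length(ix),
      farthest_idx = far, farthest_km = d[far],
      on_sea = if ("habitat" %in% names(track))
        any(track$habitat[ix] == "sea") else FALSE)
  }
  if (!length(out)) {
    return(data.frame(start_idx = integer(0), end_idx = integer(0),
                      start_ts = as.POSIXct(character(0), tz = "UTC"),
                      end_ts = as.POSIXct(character(0), tz = "UTC"),
                      duration_days = numeric(0), n_fixes = integer(0),
                      farthest_idx = integer(0), farthest_km = numeric(0),
                      on_sea = logical(0)))
  }
  do.call(rbind, out)
}

#' Classify trips into excursions, commuting trips and border movements
#'
#' A trip is an outlier when its farthest distance exceeds the Hampel
#' bound. Outlier trips under 7 days are excursions; excursions with any
#' fix on the sea ice are commuting trips; all other trips are border
#' movements.
#'
#' @param trips output of [detect_trips()].
#' @param bound a [hampel_bound()] computed from the same animal-season
#'   distance series.
#' @param animal_id,season metadata columns.
#' @return the trips data.frame with added columns is_outlier and kind.
#' @export
classify_excursions <- function(trips, bound, animal_id = NA_character_,
                                season = NA_character_) {
  is_outlier <- trips$farthest_km > bound$bound_km
  kind <- rep("border-movement", nrow(trips))
  exc <- is_outlier & trips$duration_days < 7
  kind[exc] <- ifelse(trips$on_sea[exc], "commuting", "excursion")
  cbind(data.frame(animal_id = rep(animal_id, nrow(trips)),
                   season = rep(season, nrow(trips))),
        trips, is_outlier = is_outlier, kind = kind)
}

#' Excursion frequency per week
#'
#' Raw excursion counts are not comparable across animals tracked for
#' different lengths of time, so counts are rated per 7 tracked days.
#'
#' @param n_events excursion count.
#' @param span_days tracked days in the animal-season (> 0).
#' @return events per week.
#' @export
weekly_frequency <- function(n_events, span_days) {
  if (any(span_days <= 0)) stop("tracking span must be positive")
  n_events / (span_days / 7)
}

#' Full excursion analysis for one resident animal-season
#'
#' Chains [centroid_distances()], [hampel_bound()], [detect_trips()] and
#' [classify_excursions()], then computes weekly frequencies for land
#' excursions alone and for excursions plus commuting trips (the two
#' standard reporting variants).
#'
#' With `refine = TRUE` (default) the range is first re-estimated from
#' the fixes whose centroid distance stays below a pinned log-scale
#' Hampel bound. A single far bout otherwise stretches the adaptive
#' radius a (a quantile of pairwise distances) until the 95% isopleth
#' swallows parts of the excursion corridor — the automated counterpart
#' of the interactive practice of tuning a to exclude unused areas. The
#' refit is skipped when it would discard more than 20% of the fixes.
#'
#' @param track one animal-season `fox_track`.
#' @param ud its `fox_ud` (estimated from all season fixes).
#' @param k,transform passed to [hampel_bound()].
#' @param refine logical; re-estimate the range without far outliers
#'   before trip detection.
#' @return list: `events` (classified trips), `bound`, `ud` (the
#'   possibly refined UD actually used), `freq` (data.frame: span_days,
#'   n_excursion, n_commuting, excursions_per_week, all_trips_per_week).
#' @export
analyze_excursions <- function(track, ud, k = 3, transform = "auto",
                               refine = TRUE) {
  if (refine) {
    d0 <- centroid_distances(track, ud)
    b0 <- hampel_bound(d0, k = k, transform = "log")
    keep <- d0 <= b0$bound_km
    if (any(!keep) && mean(keep) >= 0.8) {
      ud <- estimate_ud(cbind(track$x, track$y)[keep, , drop = FALSE],
                        levels = ud$levels, animal_id = ud$animal_id,
                        season = ud$season)
    }
  }
  d <- centroid_distances(track, ud)
  bound <- hampel_bound(d, k = k, transform = transform)
  trips <- detect_trips(track, ud)
  ev <- classify_excursions(trips, bound, track$animal_id[1],
                            season = NA_character_)
  span <- as.numeric(difftime(track$timestamp[nrow(track)],
                              track$timestamp[1], units = "days")) + 1
  n_exc <- sum(ev$kind == "excursion")
  n_com <- sum(ev$kind == "commuting")
  list(events = ev, bound = bound, ud = ud,
       freq = data.frame(animal_id = track$animal_id[1],
                         span_days = span,
                         n_excursion = n_exc, n_commuting = n_com,
                         excursions_per_week = weekly_frequency(n_exc, span),
                         all_trips_per_week =
                           weekly_frequency(n_exc + n_com, span)))
}
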