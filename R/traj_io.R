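# Telemetry ingestion: CSV reading, projection, daily thinning, season
# assignment, habitat classification and a simple speed-based QC filter.
#
# A track is a data.frame (class "fox_track") with columns
# animal_id, species, timestamp (POSIXct, UTC), x, y (planar km) and
# optionally habitat; rows strictly increasing in time.

EARTH_RADIUS_KM <- 6371.0088

new_track <- function(df, thinned = FALSE) {
  stopifnot(all(c("animal_id", "species", "timestamp", "x", "y") %in% names(df)))
  df <- df[order(df$timestamp), , drop = FALSE]
  if (anyDuplicated(df$timestamp)) {
    df <- df[!duplicated(df$timestamp), , drop = FALSE]
  }
  rownames(df) <- NULL
  attr(df, "thinned") <- thinned
  class(df) <- c("fox_track", "data.frame")
  df
}

is_thinned <- function(track) isTRUE(attr(track, "thinned"))

#' Project longitude/latitude to a local equal-area plane
#'
#' Lambert azimuthal equal-area projection on the authalic sphere,
#' centred at `center` (lon, lat in degrees). Preserves areas, which are
#' first-class outputs of hull-based home-range estimation; a local
#' azimuthal centre avoids UTM zone distortion at high latitudes.
#'
#' @param lon,lat numeric degrees.
#' @param center length-2 numeric (lon0, lat0) in degrees.
#' @return two-column matrix of x (km east) and y (km north).
#' @export
project_laea <- function(lon, lat, center) {
  d <- pi / 180
  l0 <- center[1] * d; p0 <- center[2] * d
  l <- lon * d; p <- lat * d
  kden <- 1 + sin(p0) * sin(p) + cos(p0) * cos(p) * cos(l - l0)
  k <- sqrt(2 / kden)
  x <- EARTH_RADIUS_KM * k * cos(p) * sin(l - l0)
  y <- EARTH_RADIUS_KM * k *
    (cos(p0) * sin(p) - sin(p0) * cos(p) * cos(l - l0))
  cbind(x = x, y = y)
}

#' Read telemetry fixes from CSV
#'
#' Expects columns `animal_id`, `species`, `timestamp` (ISO-8601, UTC
#' assumed) and either `lon`/`lat` (degrees, projected to a local
#' equal-area plane) or `x_km`/`y_km` (passed through unchanged).
#' Malformed rows (unparseable timestamp, missing coordinate) are
#' reported in the `rejected` attribute, never silently dropped.
#'
#' @param path CSV file.
#' @param center optional projection centre (lon, lat); defaults to the
#'   centroid of the valid fixes.
#' @return named list of `fox_track`, one per animal, with attributes
#'   `rejected` (data.frame of bad rows with a `reason` column) and
#'   `center` (the projection centre used, NULL for planar input).
#' @export
read_telemetry <- function(path, center = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "species", "timestamp")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("missing required column(s): ",
                         paste(miss, collapse = ", "))
  planar <- all(c("x_km", "y_km") %in% names(raw))
  if (!planar && !all(c("lon", "lat") %in% names(raw))) {
    stop("need either lon/lat or x_km/y_km columns")
  }
  ts <- as.POSIXct(raw$timestamp, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                                  "%Y-%m-%d"))
  cx <- if (planar) suppressWarnings(as.numeric(raw$x_km)) else
    suppressWarnings(as.numeric(raw$lon))
  cy <- if (planar) suppressWarnings(as.numeric(raw$y_km)) else
    suppressWarnings(as.numeric(raw$lat))
  bad <- is.na(ts) | !is.finite(cx) | !is.finite(cy)
  reason <- ifelse(is.na(ts), "unparseable timestamp", "non-finite coordinate")
  rejected <- cbind(raw[bad, , drop = FALSE],
                    reason = reason[bad])
  raw <- raw[!bad, , drop = FALSE]
  ts <- ts[!bad]; cx <- cx[!bad]; cy <- cy[!bad]
  if (planar) {
    xy <- cbind(x = cx, y = cy)
    center <- NULL
  } else {
    if (is.null(center)) center <- c(mean(cx), mean(cy))
    xy <- project_laea(cx, cy, center)
  }
  df <- data.frame(animal_id = as.character(raw$animal_id),
                   species = as.character(raw$species),
                   timestamp = ts, x = xy[, 1], y = xy[, 2],
                   stringsAsFactors = FALSE)
  tracks <- lapply(split(df, df$animal_id), new_track)
  attr(tracks, "rejected") <- rejected
  attr(tracks, "center") <- center
  tracks
}

#' Write tracks to the telemetry CSV dialect
#'
#' @param tracks a `fox_track` or list of them.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_telemetry <- function(tracks, path) {
  if (inherits(tracks, "fox_track")) tracks <- list(tracks)
  df <- do.call(rbind, lapply(tracks, function(t) {
    data.frame(animal_id = t$animal_id, species = t$species,
               timestamp = format(t$timestamp, "%Y-%m-%dT%H:%M:%S",
                                  tz = "UTC"),
               x_km = t$x, y_km = t$y, stringsAsFactors = FALSE)
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Stable per-animal RNG stream: polynomial hash of the id folded with the
# master seed, below 2^31 so set.seed() is safe. Adding an animal to a
# data set never changes another animal's stream.
animal_seed <- function(master_seed, animal_id) {
  p <- 2147483629
  h <- 0
  for (b in utf8ToInt(animal_id)) h <- (h * 31 + b) %% p
  as.integer((h + (master_seed %% p)) %% p)
}

#' Thin a track to one fix per day
#'
#' Keeps exactly one uniformly random fix per local calendar day (days
#' with no fixes stay empty), matching an analysis resolution set by the
#' lowest collar duty cycle. Deterministic given the seed; each animal
#' gets an independent RNG stream derived from the master seed and its
#' id. Thinning an already-thinned track is the identity.
#'
#' @param track a `fox_track`.
#' @param seed master integer seed.
#' @param day_offset_hours local-time offset (hours) defining calendar
#'   day boundaries; default -6 (central Canada).
#' @return thinned `fox_track`.
#' @export
thin_daily <- function(track, seed, day_offset_hours = -6) {
  if (nrow(track) == 0) stop("cannot thin an empty track")
  day <- as.Date(track$timestamp + day_offset_hours * 3600, tz = "UTC")
  keep <- withr::with_seed(
    animal_seed(seed, track$animal_id[1]),
    vapply(split(seq_len(nrow(track)), day),
           function(ix) if (length(ix) == 1) ix else ix[sample.int(length(ix), 1)],
           integer(1)))
  new_track(track[sort(keep), , drop = FALSE], thinned = TRUE)
}

#' Default season windows
#'
#' Summer (resource abundance, geese present) runs May 15 - October 31;
#' winter (resource scarcity) November 1 - May 14. The two windows
#' partition the year.
#'
#' @return list of windows, each `list(label, start, end)` with month-day
#'   strings.
#' @export
season_windows <- function() {
  list(list(label = "summer", start = "05-15", end = "10-31"),
       list(label = "winter", start = "11-01", end = "05-14"))
}

md_num <- function(md) {
  p <- as.integer(strsplit(md, "-", fixed = TRUE)[[1]])
  p[1] * 100L + p[2]
}

#' Assign a season label to timestamps
#'
#' @param timestamps POSIXct vector.
#' @param windows season windows as from [season_windows()].
#' @return character vector of labels.
#' @export
assign_season <- function(timestamps, windows = season_windows()) {
  lt <- as.POSIXlt(timestamps, tz = "UTC")
  md <- (lt$mon + 1L) * 100L + lt$mday
  out <- rep(NA_character_, length(md))
  for (w in windows) {
    s <- md_num(w$start); e <- md_num(w$end)
    hit <- if (s <= e) md >= s & md <= e else md >= s | md <= e
    out[hit] <- w$label
  }
  out
}

#' Label animal-season instances
#'
#' A season instance is a specific season of a specific year, e.g.
#' "winter-2017" for the winter starting November 2017 (its January-May
#' part belongs to the same instance). Summer instances carry their own
#' calendar year.
#'
#' @inheritParams assign_season
#' @return character vector like "summer-2018".
#' @export
season_instance <- function(timestamps, windows = season_windows()) {
  lab <- assign_season(timestamps, windows)
  lt <- as.POSIXlt(timestamps, tz = "UTC")
  yr <- lt$year + 1900L
  md <- (lt$mon + 1L) * 100L + lt$mday
  for (w in windows) {
    s <- md_num(w$start); e <- md_num(w$end)
    if (s > e) {                       # wrapping window: early part -> year - 1
      wrap <- lab == w$label & md <= e
      yr[wrap] <- yr[wrap] - 1L
    }
  }
  paste(lab, yr, sep = "-")
}

#' Classify fix habitat from world polygons
#'
#' Point-in-polygon against land, forest and sea (in that priority
#' order: a point exactly on the coastline is land). Points in no
#' polygon are `unknown`. Sea fixes dated outside the ice window keep
#' the `sea` label but are flagged implausible.
#'
#' @param x,y planar km coordinates.
#' @param world a `fox_world`.
#' @param timestamps optional POSIXct, needed for the implausibility flag.
#' @return character vector of labels with attribute `implausible`
#'   (logical vector).
#' @export
classify_habitat <- function(x, y, world, timestamps = NULL) {
  lab <- rep("unknown", length(x))
  lab[pip(x, y, world$sea)] <- "sea"
  lab[pip(x, y, world$forest)] <- "forest"
  lab[pip(x, y, world$land)] <- "land"
  implausible <- rep(FALSE, length(x))
  if (!is.null(timestamps)) {
    doy <- as.POSIXlt(timestamps, tz = "UTC")$yday + 1L
    implausible <- lab == "sea" & !in_ice_window(doy, world)
  }
  attr(lab, "implausible") <- implausible
  lab
}

#' Remove gross location errors by implied speed
#'
#' Flags fixes whose straight-line speed to both temporal neighbours
#' exceeds `max_kmh` (a lone teleported point forces implausible speeds
#' on both sides; genuine fast travel does not). The published analyses
#' screened such errors visually; this is the explicit, reproducible
#' substitute, off by default in the pipeline.
#'
#' @param track a `fox_track`.
#' @param max_kmh speed threshold in km/h; `Inf` disables filtering.
#' @return filtered `fox_track` with attribute `rejected` (the removed
#'   rows).
#' @export
qc_speed_filter <- function(track, max_kmh = Inf) {
  n <- nrow(track)
  if (n < 3 || !is.finite(max_kmh)) {
    attr(track, "rejected") <- track[0, , drop = FALSE]
    return(track)
  }
  dt <- diff(as.numeric(track$timestamp)) / 3600
  dd <- sqrt(diff(track$x)^2 + diff(track$y)^2)
  v <- dd / pmax(dt, 1e-9)
  bad <- c(FALSE, v[-1] > max_kmh & v[-length(v)] > max_kmh, FALSE)
  out <- new_track(track[!bad, , drop = FALSE], thinned = is_thinned(track))
  attr(out, "rejected") <- track[bad, , drop = FALSE]
  out
}
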