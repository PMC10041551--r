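# Shared fixtures, built in code at test time.

unit_square <- function(x0 = 0, y0 = 0, s = 1) {
  cbind(c(x0, x0 + s, x0 + s, x0), c(y0, y0, y0 + s, y0 + s))
}

grid5 <- function() {
  as.matrix(expand.grid(x = 0:4, y = 0:4))
}

# A minimal synthetic track straight north at fixed speed, one fix/day.
straight_track <- function(n = 10, speed = 10, id = "S1", species = "red",
                           start = "2017-11-01", habitat = "land") {
  ts <- as.POSIXct(paste(start, "12:00:00"), tz = "UTC") +
    (seq_len(n) - 1) * 86400
  foxmove:::new_track(data.frame(
    animal_id = id, species = species, timestamp = ts,
    x = 0, y = (seq_len(n) - 1) * speed, habitat = habitat,
    stringsAsFactors = FALSE), thinned = TRUE)
}

# Track from explicit coordinates (one fix/day).
xy_track <- function(x, y, id = "T1", species = "red",
                     start = "2017-11-01", habitat = NULL) {
  ts <- as.POSIXct(paste(start, "12:00:00"), tz = "UTC") +
    (seq_along(x) - 1) * 86400
  df <- data.frame(animal_id = id, species = species, timestamp = ts,
                   x = x, y = y, stringsAsFactors = FALSE)
  if (!is.null(habitat)) df$habitat <- habitat
  foxmove:::new_track(df, thinned = TRUE)
}

# Brute-force a-LoCoH neighbour sets: for each root, neighbours added in
# increasing distance while cumulative distance <= a.
brute_members <- function(pts, a) {
  n <- nrow(pts)
  lapply(seq_len(n), function(i) {
    d <- sqrt((pts[, 1] - pts[i, 1])^2 + (pts[, 2] - pts[i, 2])^2)
    nb <- setdiff(order(d), i)          # ascending distance, root removed
    keep <- nb[cumsum(d[nb]) <= a]
    sort(c(i, keep))
  })
}

# Monte-Carlo area of a union of convex hulls (independent of the slab
# machinery), on a bounding box with nsamp uniform points.
mc_union_area <- function(hulls, nsamp = 2e5, seed = 99) {
  v <- do.call(rbind, hulls)
  xr <- range(v[, 1]); yr <- range(v[, 2])
  withr::with_seed(seed, {
    pts <- cbind(stats::runif(nsamp, xr[1], xr[2]),
                 stats::runif(nsamp, yr[1], yr[2]))
  })
  mean(foxmove:::points_in_hulls(pts, hulls)) *
    diff(xr) * diff(yr)
}

demo_world <- function() default_world()
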