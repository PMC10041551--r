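# Adaptive local convex hull (a-LoCoH) utilization distributions.
#
# For every fix ("root") a local hull is the convex hull of the root and
# its nearest neighbours, neighbours being accumulated in increasing
# Euclidean distance while their cumulative distance stays within `a`
# (adaptive method; k and r variants also provided). Hulls sorted by a
# density proxy (ascending area) are unioned until the union covers the
# requested fraction of fixes; that union is the isopleth. With the time
# scaling s fixed at 0, time-scaled distance reduces to plain Euclidean
# distance, which is the only variant implemented.

#' LoCoH parameter bundle
#'
#' @param method one of "a" (adaptive, cumulative-distance radius),
#'   "k" (fixed neighbour count), "r" (fixed radius).
#' @param a,k,r the tuning value matching `method` (km for a and r).
#' @param s time-scaling exponent; only 0 (pure Euclidean) is supported.
#' @param isopleth_levels utilization fractions; defaults to the 50%
#'   core area and 95% home range.
#' @return object of class `locoh_params`.
#' @export
locoh_params <- function(method = c("a", "k", "r"), a = NULL, k = NULL,
                         r = NULL, s = 0, isopleth_levels = c(0.50, 0.95)) {
  method <- match.arg(method)
  if (s != 0) stop("only s = 0 (Euclidean distance) is supported")
  val <- switch(method, a = a, k = k, r = r)
  if (is.null(val) || !is.finite(val) || val <= 0) {
    stop("parameter '", method, "' must be a positive number")
  }
  if (any(isopleth_levels <= 0 | isopleth_levels > 1)) {
    stop("isopleth levels must lie in (0, 1]")
  }
  structure(list(method = method, a = a, k = k, r = r, s = 0,
                 isopleth_levels = sort(isopleth_levels)),
            class = "locoh_params")
}

#' Select the adaptive radius a from the data
#'
#' The published workflow tuned a per animal with interactive graph
#' tools, which is not reproducible; the package substitutes a stated
#' rule: a is a quantile of the pairwise inter-fix distances (default
#' the maximum, the common conservative choice that keeps every hull
#' connected to the bulk of the data).
#'
#' @param points two-column fix matrix (km).
#' @param quantile fraction in (0, 1]; 1 gives the maximum pairwise
#'   distance.
#' @return the selected a (km).
#' @export
select_a <- function(points, quantile = 1.0) {
  if (nrow(points) < 2) stop("need at least 2 points to select a")
  d <- stats::dist(points)
  as.numeric(stats::quantile(d, probs = quantile, names = FALSE))
}

#' Construct local hulls around every fix
#'
#' @param points two-column fix matrix (km).
#' @param params a [locoh_params()] bundle.
#' @return list of class `locoh_hulls`: for each root, the hull vertex
#'   matrix (counter-clockwise; fewer than 3 rows marks a degenerate
#'   zero-area hull, retained and flagged), its area, the number of
#'   member points, and the root index.
#' @export
local_hulls <- function(points, params) {
  n <- nrow(points)
  if (n < 3) stop("need at least 3 points")
  ctr <- sweep(points, 2, colMeans(points))
  if (min(svd(ctr, nu = 0, nv = 0)$d) < 1e-9 * max(abs(ctr), 1)) {
    stop("all points are collinear: local hulls are degenerate everywhere")
  }
  dm <- as.matrix(stats::dist(points))
  hulls <- vector("list", n)
  for (i in seq_len(n)) {
    d <- dm[i, ]
    ord <- order(d)                     # root itself first (distance 0)
    nb <- ord[-1]                       # remaining points, nearest first
    take <- switch(params$method,
      a = nb[cumsum(d[nb]) <= params$a],
      k = nb[seq_len(min(params$k - 1L, length(nb)))],
      r = nb[d[nb] <= params$r])
    member <- c(i, take)
    h <- convex_hull(points[member, , drop = FALSE])
    hulls[[i]] <- list(hull = h, area = poly_area(h),
                       n_members = length(member), root = i)
  }
  structure(hulls, class = "locoh_hulls", points = points, params = params)
}

# Density-proxy ordering: ascending area, ties by more enclosed points,
# then root index.
order_hulls <- function(hulls, points) {
  area <- vapply(hulls, `[[`, numeric(1), "area")
  encl <- vapply(hulls, function(h) {
    if (nrow(h$hull) < 3) return(1L)
    sum(points_in_convex(points, h$hull))
  }, numeric(1))
  root <- vapply(hulls, `[[`, numeric(1), "root")
  order(area, -encl, root)
}

#' Build utilization-distribution isopleths from local hulls
#'
#' Hulls are accumulated in density order until the union covers at
#' least `ceiling(level * n)` fixes (a fix counts as covered when inside
#' or on the boundary of any accumulated hull); each isopleth is the
#' union at that point. Nesting and area monotonicity across levels hold
#' by construction since lower levels are prefixes of higher ones.
#'
#' @param hulls a `locoh_hulls` set.
#' @param points the fix matrix the hulls were built from.
#' @param levels utilization fractions in (0, 1].
#' @param animal_id,season metadata carried into the result.
#' @return object of class `fox_ud`: isopleth hull lists, exact union
#'   areas (km^2), the 95%-isopleth (or highest-level) centroid, fix
#'   count and parameters.
#' @export
build_isopleths <- function(hulls, points, levels = c(0.50, 0.95),
                            animal_id = NA_character_,
                            season = NA_character_) {
  if (any(levels <= 0 | levels > 1)) stop("levels must lie in (0, 1]")
  levels <- sort(levels)
  n <- nrow(points)
  ord <- order_hulls(hulls, points)
  covered <- rep(FALSE, n)
  n_covered <- integer(length(ord))
  polys <- lapply(hulls, `[[`, "hull")[ord]
  for (m in seq_along(ord)) {
    h <- polys[[m]]
    if (nrow(h) >= 3) {
      todo <- which(!covered)
      if (length(todo)) {
        covered[todo] <- points_in_convex(points[todo, , drop = FALSE], h)
      }
    } else {
      # degenerate hull still covers its own members (zero area)
      covered[hulls[[ord[m]]]$root] <- TRUE
    }
    n_covered[m] <- sum(covered)
  }
  iso <- vector("list", length(levels))
  areas <- numeric(length(levels))
  centroids <- matrix(NA_real_, length(levels), 2)
  n_hulls <- integer(length(levels))
  for (li in seq_along(levels)) {
    need <- ceiling(levels[li] * n)
    m <- match(TRUE, n_covered >= need)
    if (is.na(m)) m <- length(ord)      # cannot happen: all hulls cover all roots
    n_hulls[li] <- m
    iso[[li]] <- polys[seq_len(m)]
    um <- union_measures(iso[[li]])
    areas[li] <- um$area
    centroids[li, ] <- um$centroid
  }
  names(iso) <- names(areas) <- format(levels)
  structure(list(animal_id = animal_id, season = season, levels = levels,
                 isopleths = iso, areas = areas, centroids = centroids,
                 centroid = centroids[length(levels), ],
                 n_fixes = n, n_hulls = n_hulls,
                 n_degenerate = sum(vapply(hulls, function(h)
                   nrow(h$hull) < 3, logical(1))),
                 params = attr(hulls, "params")),
            class = "fox_ud")
}

#' Estimate an a-LoCoH utilization distribution in one call
#'
#' Convenience wrapper: selects a (unless given), builds local hulls and
#' isopleths.
#'
#' @param points two-column fix matrix (km).
#' @param levels isopleth fractions.
#' @param a adaptive radius; selected by [select_a()] when NULL.
#' @param a_quantile passed to [select_a()].
#' @param animal_id,season metadata.
#' @return a `fox_ud`.
#' @export
estimate_ud <- function(points, levels = c(0.50, 0.95), a = NULL,
                        a_quantile = 1.0, animal_id = NA_character_,
                        season = NA_character_) {
  if (is.null(a)) a <- select_a(points, a_quantile)
  par <- locoh_params("a", a = a, isopleth_levels = levels)
  hl <- local_hulls(points, par)
  build_isopleths(hl, points, levels, animal_id, season)
}

ud_level_index <- function(ud, level) {
  i <- match(TRUE, abs(ud$levels - level) < 1e-9)
  if (is.na(i)) stop("isopleth level ", level, " not present in this UD")
  i
}

#' Isopleth area of a utilization distribution
#' @param ud a `fox_ud`.
#' @param level isopleth fraction.
#' @return area in km^2.
#' @export
ud_area <- function(ud, level = 0.95) ud$areas[ud_level_index(ud, level)]

#' Test points against an isopleth
#' @param ud a `fox_ud`.
#' @param pts two-column point matrix.
#' @param level isopleth fraction.
#' @return logical vector, TRUE when inside or on the isopleth boundary.
#' @export
ud_contains <- function(ud, pts, level = 0.95) {
  points_in_hulls(pts, ud$isopleths[[ud_level_index(ud, level)]])
}

#' @export
print.fox_ud <- function(x, ...) {
  cat("a-LoCoH utilization distribution",
      if (!is.na(x$animal_id)) paste0("(", x$animal_id,
        if (!is.na(x$season)) paste0(", ", x$season), ")"), "\n")
  cat("  fixes:", x$n_fixes, " a:",
      format(x$params$a, digits = 4), "km\n")
  for (i in seq_along(x$levels)) {
    cat(sprintf("  %3.0f%% isopleth: %8.3f km^2 (%d hulls)\n",
                100 * x$levels[i], x$areas[i], x$n_hulls[i]))
  }
  invisible(x)
}

#' Seasonal home-range shift between two utilization distributions
#'
#' For each shared isopleth level reports the intersection-over-union
#' overlap, both directional overlap fractions (intersection over each
#' UD's own area), their mean (the default single "overlap" figure), and
#' the Euclidean distance between the isopleth centroids.
#'
#' @param ud_a,ud_b two `fox_ud` for the same animal (e.g. summer and
#'   winter).
#' @return data.frame with one row per level: `level`, `overlap_pct`
#'   (mean of directional), `overlap_iou_pct`, `overlap_a_pct`,
#'   `overlap_b_pct`, `centroid_distance_km`.
#' @export
seasonal_shift <- function(ud_a, ud_b) {
  levels <- intersect(format(ud_a$levels), format(ud_b$levels))
  if (!length(levels)) stop("the two UDs share no isopleth level")
  out <- do.call(rbind, lapply(levels, function(lv) {
    lvl <- as.numeric(lv)
    ia <- ud_level_index(ud_a, lvl); ib <- ud_level_index(ud_b, lvl)
    inter <- intersection_area(ud_a$isopleths[[ia]], ud_b$isopleths[[ib]])
    aa <- ud_a$areas[ia]; ab <- ud_b$areas[ib]
    uni <- aa + ab - inter
    da <- if (aa > 0) 100 * inter / aa else NA_real_
    db <- if (ab > 0) 100 * inter / ab else NA_real_
    data.frame(level = lvl,
               overlap_pct = mean(c(da, db)),
               overlap_iou_pct = if (uni > 0) 100 * inter / uni else NA_real_,
               overlap_a_pct = da, overlap_b_pct = db,
               centroid_distance_km =
                 sqrt(sum((ud_a$centroids[ia, ] - ud_b$centroids[ib, ])^2)))
  }))
  rownames(out) <- NULL
  out
}

#' Sample-size asymptote diagnostic for home-range area
#'
#' Recomputes the 95% isopleth area on growing track prefixes and finds
#' the smallest prefix length whose area stays within a relative
#' tolerance band of the full-data area for every larger prefix. Tracks
#' that keep expanding (e.g. drifting animals) never enter the band
#' early and are flagged as not having reached an asymptote.
#'
#' @param points fix matrix in time order.
#' @param min_required minimum fixes for the analysis (default 38, the
#'   average sample size at which resident ranges stabilise).
#' @param step prefix-size increment.
#' @param tol relative tolerance band around the full-data area.
#' @param a adaptive radius; by default selected once from the full data
#'   so prefix areas are comparable.
#' @return list: `status` ("ok", "no_asymptote" or "insufficient"),
#'   `asymptote_n` (NA unless "ok"), `curve` (data.frame n, area_km2,
#'   ratio), `full_area`.
#' @export
area_asymptote <- function(points, min_required = 38L, step = 5L,
                           tol = 0.05, a = NULL) {
  n <- nrow(points)
  if (n < min_required) {
    return(list(status = "insufficient", asymptote_n = NA_integer_,
                curve = data.frame(n = integer(0), area_km2 = numeric(0),
                                   ratio = numeric(0)),
                full_area = NA_real_))
  }
  if (is.null(a)) a <- select_a(points, 1.0)
  ns <- unique(c(seq(min_required, n, by = step), n))
  areas <- vapply(ns, function(m) {
    ud <- estimate_ud(points[seq_len(m), , drop = FALSE], levels = 0.95,
                      a = a)
    ud_area(ud, 0.95)
  }, numeric(1))
  full <- areas[length(areas)]
  ratio <- areas / full
  in_band <- abs(ratio - 1) <= tol
  # smallest n from which every later prefix stays in the band
  ok_from <- rev(cumprod(rev(in_band))) > 0
  first <- match(TRUE, ok_from)
  curve <- data.frame(n = ns, area_km2 = areas, ratio = ratio)
  if (is.na(first) || ns[first] >= n) {
    return(list(status = "no_asymptote", asymptote_n = NA_integer_,
                curve = curve, full_area = full))
  }
  list(status = "ok", asymptote_n = ns[first], curve = curve,
       full_area = full)
}

#' Write utilization-distribution isopleths as GeoJSON
#'
#' One Feature per isopleth level. The geometry is the MultiPolygon of
#' the contributing local hulls (components may overlap; the `area_km2`
#' property is the exact area of their union, not the sum of parts).
#'
#' @param ud a `fox_ud`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ud_geojson <- function(ud, path) {
  feats <- lapply(seq_along(ud$levels), function(i) {
    comps <- Filter(function(h) nrow(h) >= 3, ud$isopleths[[i]])
    coords <- lapply(comps, function(h) {
      ring <- rbind(h, h[1, , drop = FALSE])
      list(lapply(seq_len(nrow(ring)), function(r) c(ring[r, 1], ring[r, 2])))
    })
    list(type = "Feature",
         properties = list(animal = ud$animal_id, season = ud$season,
                           level = ud$levels[i],
                           area_km2 = ud$areas[i],
                           n_fixes = ud$n_fixes),
         geometry = list(type = "MultiPolygon", coordinates = coords))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}
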