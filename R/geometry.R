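# Planar geometry for hull-based utilization distributions.
#
# All coordinates are planar kilometres. Isopleths are unions of convex
# local hulls; their areas, intersections and centroids are computed by
# exact vertical slab decomposition: between consecutive critical
# x-coordinates (vertices and edge crossings) every interval endpoint is
# linear in x, so 2-point Gauss-Legendre integrates the covered length
# (and its first moments) exactly up to floating point.

# Convex hull of a point matrix, counter-clockwise, no repeated closing row.
# Collinear / tiny inputs return the (<=2-row) unique point matrix: a
# degenerate hull with zero area.
convex_hull <- function(pts) {
  pts <- unique(round(pts, 12))
  if (nrow(pts) < 3) return(pts)
  idx <- grDevices::chull(pts[, 1], pts[, 2])
  h <- pts[idx, , drop = FALSE]
  if (nrow(h) < 3) return(h)
  if (shoelace(h) < 0) h <- h[rev(seq_len(nrow(h))), , drop = FALSE]
  h
}

# Signed shoelace area (positive for counter-clockwise rings).
shoelace <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  j <- c(seq_len(nrow(poly))[-1], 1L)
  sum(x * y[j] - x[j] * y) / 2
}

#' Area of a simple polygon
#'
#' Unsigned planar area of a polygon given as a two-column vertex matrix
#' (ring not closed). Degenerate inputs (< 3 vertices) have area 0.
#'
#' @param poly numeric matrix with columns x, y.
#' @return area in squared coordinate units.
#' @export
poly_area <- function(poly) {
  if (is.null(poly) || nrow(poly) < 3) return(0)
  abs(shoelace(poly))
}

# Vectorised point-in-convex-polygon test; boundary counts as inside.
# `poly` must be counter-clockwise.
points_in_convex <- function(pts, poly, tol = 1e-9) {
  n <- nrow(poly)
  if (n < 3) return(rep(FALSE, nrow(pts)))
  inside <- rep(TRUE, nrow(pts))
  scale <- max(abs(poly), 1)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    cr <- (poly[j, 1] - poly[i, 1]) * (pts[, 2] - poly[i, 2]) -
          (poly[j, 2] - poly[i, 2]) * (pts[, 1] - poly[i, 1])
    inside <- inside & (cr >= -tol * scale)
    if (!any(inside)) break
  }
  inside
}

# Which points are covered by at least one hull in a list.
points_in_hulls <- function(pts, hulls) {
  covered <- rep(FALSE, nrow(pts))
  for (h in hulls) {
    if (is.null(h) || nrow(h) < 3) next
    todo <- which(!covered)
    if (!length(todo)) break
    covered[todo] <- points_in_convex(pts[todo, , drop = FALSE], h)
  }
  covered
}

# Drop hulls entirely contained in a single other hull (they cannot change
# the union). Cheap O(n^2) filter that keeps slab decomposition small.
prune_contained <- function(hulls) {
  areas <- vapply(hulls, poly_area, numeric(1))
  keep <- areas > 0
  live <- which(keep)
  if (length(live) < 2) return(hulls[keep])
  ord <- live[order(areas[live])]                 # small ones pruned first
  big <- live[order(-areas[live])]
  for (i in ord) {
    for (j in big) {
      if (j == i || areas[j] < areas[i] || !keep[j]) next
      if (all(points_in_convex(hulls[[i]], hulls[[j]]))) { keep[i] <- FALSE; break }
    }
  }
  hulls[keep]
}

# Flatten a hull list to an edge table: x1 y1 x2 y2 id.
hulls_edges <- function(hulls) {
  out <- vector("list", length(hulls))
  for (k in seq_along(hulls)) {
    h <- hulls[[k]]
    if (is.null(h) || nrow(h) < 3) next
    n <- nrow(h)
    j <- c(seq_len(n)[-1], 1L)
    out[[k]] <- cbind(h[, 1], h[, 2], h[j, 1], h[j, 2], k)
  }
  do.call(rbind, out)
}

# x-coordinates of all pairwise proper segment crossings among edges.
edge_crossings_x <- function(ed) {
  m <- nrow(ed)
  if (m < 2) return(numeric(0))
  ij <- utils::combn(m, 2L)
  i <- ij[1, ]; j <- ij[2, ]
  px <- ed[i, 1]; py <- ed[i, 2]; rx <- ed[i, 3] - px; ry <- ed[i, 4] - py
  qx <- ed[j, 1]; qy <- ed[j, 2]; sx <- ed[j, 3] - qx; sy <- ed[j, 4] - qy
  den <- rx * sy - ry * sx
  ok <- abs(den) > 1e-14
  t <- ((qx - px) * sy - (qy - py) * sx) / den
  u <- ((qx - px) * ry - (qy - py) * rx) / den
  ok <- ok & t >= 0 & t <= 1 & u >= 0 & u <= 1
  (px + t * rx)[which(ok)]
}

# y-intervals cut by the vertical line at x through each hull, returned as
# a 2-col matrix (lo, hi), one row per hull crossed. `ed` is an edge table.
slab_hull_intervals <- function(ed, x) {
  sel <- (pmin(ed[, 1], ed[, 3]) <= x) & (pmax(ed[, 1], ed[, 3]) >= x) &
         (ed[, 1] != ed[, 3])
  if (!any(sel)) return(matrix(numeric(0), 0, 2))
  e <- ed[sel, , drop = FALSE]
  y <- e[, 2] + (x - e[, 1]) * (e[, 4] - e[, 2]) / (e[, 3] - e[, 1])
  lo <- tapply(y, e[, 5], min)
  hi <- tapply(y, e[, 5], max)
  cbind(as.numeric(lo), as.numeric(hi))
}

# Merge intervals into a disjoint sorted set.
iv_merge <- function(iv) {
  if (nrow(iv) == 0) return(iv)
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  lo <- iv[1, 1]; hi <- iv[1, 2]
  out <- matrix(numeric(0), 0, 2)
  for (r in seq_len(nrow(iv))[-1]) {
    if (iv[r, 1] <= hi) hi <- max(hi, iv[r, 2])
    else { out <- rbind(out, c(lo, hi)); lo <- iv[r, 1]; hi <- iv[r, 2] }
  }
  rbind(out, c(lo, hi))
}

iv_length <- function(iv) if (nrow(iv) == 0) 0 else sum(iv[, 2] - iv[, 1])

# Intersection of two disjoint sorted interval sets.
iv_intersect <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(matrix(numeric(0), 0, 2))
  out <- matrix(numeric(0), 0, 2)
  for (i in seq_len(nrow(a))) {
    lo <- pmax(a[i, 1], b[, 1]); hi <- pmin(a[i, 2], b[, 2])
    k <- hi > lo
    if (any(k)) out <- rbind(out, cbind(lo[k], hi[k]))
  }
  out
}

# Critical x grid for one or two hull sets.
slab_grid <- function(ed) {
  xs <- c(ed[, 1], ed[, 3], edge_crossings_x(ed))
  xs <- sort(unique(xs))
  xs[c(TRUE, diff(xs) > 1e-12)]
}

#' Area and centroid of a union of convex hulls
#'
#' Exact (to floating point) area and area-weighted centroid of the union
#' of a list of convex polygons, via vertical slab decomposition. Hulls
#' with fewer than three vertices contribute nothing.
#'
#' @param hulls list of two-column counter-clockwise vertex matrices.
#' @return list with `area`, `centroid` (length-2 numeric, NA when the
#'   union has zero area).
#' @export
union_measures <- function(hulls) {
  hulls <- prune_contained(hulls)
  ed <- hulls_edges(hulls)
  if (is.null(ed) || nrow(ed) == 0) {
    return(list(area = 0, centroid = c(NA_real_, NA_real_)))
  }
  m <- cpp_union_measures(ed)
  if (m[1] <= 0) return(list(area = 0, centroid = c(NA_real_, NA_real_)))
  list(area = m[1], centroid = c(m[2] / m[1], m[3] / m[1]))
}

# Pure-R slab implementation, retained as an independent oracle for the
# compiled path (tests cross-check the two).
union_measures_r <- function(hulls) {
  hulls <- prune_contained(hulls)
  ed <- hulls_edges(hulls)
  if (is.null(ed) || nrow(ed) == 0) {
    return(list(area = 0, centroid = c(NA_real_, NA_real_)))
  }
  xs <- slab_grid(ed)
  area <- mx <- my <- 0
  g <- 0.5 / sqrt(3)
  for (s in seq_len(length(xs) - 1L)) {
    w <- xs[s + 1L] - xs[s]
    if (w <= 1e-12) next
    mid <- (xs[s] + xs[s + 1L]) / 2
    for (xg in c(mid - g * w, mid + g * w)) {
      iv <- iv_merge(slab_hull_intervals(ed, xg))
      L <- iv_length(iv)
      area <- area + w / 2 * L
      mx <- mx + w / 2 * xg * L
      if (nrow(iv)) my <- my + w / 2 * sum(iv[, 2]^2 - iv[, 1]^2) / 2
    }
  }
  if (area <= 0) return(list(area = 0, centroid = c(NA_real_, NA_real_)))
  list(area = area, centroid = c(mx / area, my / area))
}

#' Area of a union of convex hulls
#' @inheritParams union_measures
#' @return numeric area.
#' @export
union_area <- function(hulls) union_measures(hulls)$area

#' Intersection area of two unions of convex hulls
#'
#' Area of (union of `hulls_a`) intersected with (union of `hulls_b`),
#' by the same exact slab decomposition as [union_measures()].
#'
#' @param hulls_a,hulls_b lists of convex polygon vertex matrices.
#' @return numeric area.
#' @export
intersection_area <- function(hulls_a, hulls_b) {
  hulls_a <- prune_contained(hulls_a)
  hulls_b <- prune_contained(hulls_b)
  ed_a <- hulls_edges(hulls_a)
  ed_b <- hulls_edges(hulls_b)
  if (is.null(ed_a) || is.null(ed_b) || nrow(ed_a) == 0 || nrow(ed_b) == 0) {
    return(0)
  }
  cpp_intersection_area(ed_a, ed_b)
}

# Pure-R counterpart of intersection_area (oracle path).
intersection_area_r <- function(hulls_a, hulls_b) {
  hulls_a <- prune_contained(hulls_a)
  hulls_b <- prune_contained(hulls_b)
  ed_a <- hulls_edges(hulls_a)
  ed_b <- hulls_edges(hulls_b)
  if (is.null(ed_a) || is.null(ed_b) || nrow(ed_a) == 0 || nrow(ed_b) == 0) {
    return(0)
  }
  ed <- rbind(ed_a, ed_b)
  xs <- slab_grid(ed)
  area <- 0
  g <- 0.5 / sqrt(3)
  for (s in seq_len(length(xs) - 1L)) {
    w <- xs[s + 1L] - xs[s]
    if (w <= 1e-12) next
    mid <- (xs[s] + xs[s + 1L]) / 2
    for (xg in c(mid - g * w, mid + g * w)) {
      iva <- iv_merge(slab_hull_intervals(ed_a, xg))
      ivb <- iv_merge(slab_hull_intervals(ed_b, xg))
      area <- area + w / 2 * iv_length(iv_intersect(iva, ivb))
    }
  }
  area
}

# Largest pairwise distance realised by the vertices of a hull list.
hulls_diameter <- function(hulls) {
  v <- do.call(rbind, hulls)
  if (is.null(v) || nrow(v) < 2) return(0)
  max(stats::dist(v))
}
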