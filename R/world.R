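# Simulation world: habitat polygons (planar km) and the sea-ice window.

#' Construct a simulation world
#'
#' A world is a set of pairwise non-overlapping habitat polygons — land
#' (open tundra), sea (ice-covered ocean when in season) and forest — in
#' planar kilometre coordinates, plus the day-of-year window during which
#' the sea ice is a usable movement substrate.
#'
#' Defaults mirror a low-Arctic coastal study system: the ice platform is
#' consolidated by December 2 (doy 336) and gone by July 7 (doy 188).
#'
#' @param land_polygon,sea_polygon,forest_polygon two-column vertex
#'   matrices (km), rings not closed.
#' @param ice_on_doy,ice_off_doy day-of-year the sea ice becomes / stops
#'   being available. The window wraps the year end.
#' @return an object of class `fox_world`.
#' @export
sim_world <- function(land_polygon, sea_polygon, forest_polygon,
                      ice_on_doy = 336L, ice_off_doy = 188L) {
  stopifnot(is.matrix(land_polygon), ncol(land_polygon) == 2,
            is.matrix(sea_polygon), ncol(sea_polygon) == 2,
            is.matrix(forest_polygon), ncol(forest_polygon) == 2)
  if (ice_on_doy == ice_off_doy) stop("ice window must be non-empty")
  w <- list(land = land_polygon, sea = sea_polygon, forest = forest_polygon,
            ice_on_doy = as.integer(ice_on_doy),
            ice_off_doy = as.integer(ice_off_doy))
  class(w) <- "fox_world"
  w
}

rect_poly <- function(x0, x1, y0, y1) {
  cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1))
}

#' Default coastal-tundra world
#'
#' A 6000 x 6000 km planar world: a 200 km tundra band (land) along a
#' straight east-west coastline at y = 50 km, sea to the north, boreal
#' forest to the south. Wide enough that multi-thousand-km dispersals
#' never leave the mapped area.
#'
#' @inheritParams sim_world
#' @return a `fox_world`.
#' @export
default_world <- function(ice_on_doy = 336L, ice_off_doy = 188L) {
  sim_world(land_polygon   = rect_poly(-3000, 3000, -150, 50),
            sea_polygon    = rect_poly(-3000, 3000, 50, 3000),
            forest_polygon = rect_poly(-3000, 3000, -3000, -150),
            ice_on_doy = ice_on_doy, ice_off_doy = ice_off_doy)
}

# TRUE when a day-of-year falls inside the (possibly wrapping) ice window.
in_ice_window <- function(doy, world) {
  on <- world$ice_on_doy; off <- world$ice_off_doy
  if (on <= off) doy >= on & doy <= off else doy >= on | doy <= off
}

# Point-in-polygon with boundary counted as inside (sp returns 0 outside).
pip <- function(x, y, poly) {
  sp::point.in.polygon(x, y, poly[, 1], poly[, 2]) > 0
}

#' Write world polygons as GeoJSON
#'
#' One Feature per habitat polygon, coordinates in planar km.
#'
#' @param world a `fox_world`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_world_geojson <- function(world, path) {
  feat <- function(name, poly) {
    ring <- rbind(poly, poly[1, , drop = FALSE])
    list(type = "Feature",
         properties = list(habitat = name,
                           ice_on_doy = world$ice_on_doy,
                           ice_off_doy = world$ice_off_doy),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                           function(i) c(ring[i, 1], ring[i, 2])))))
  }
  gj <- list(type = "FeatureCollection",
             features = list(feat("land", world$land),
                             feat("sea", world$sea),
                             feat("forest", world$forest)))
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}
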