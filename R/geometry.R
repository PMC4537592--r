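#' Great-circle geometry on a spherical Earth
#'
#' Distance, initial bearing, destination point and midpoint on a sphere of
#' radius 6371.0 km. Coordinates are decimal degrees (WGS-84 style, west
#' negative); bearings are degrees clockwise from geographic north.
#'
#' @name geometry
#' @keywords internal
NULL

EARTH_RADIUS_KM <- 6371.0

.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi

.check_latlon <- function(lat, lon, what = "coordinate") {
  if (any(!is.finite(lat)) || any(!is.finite(lon)))
    stop("non-finite ", what, call. = FALSE)
  if (any(lat < -90 | lat > 90))
    stop("latitude out of [-90, 90]", call. = FALSE)
  if (any(lon < -180 | lon >= 360))
    stop("longitude out of range", call. = FALSE)
  invisible(TRUE)
}

#' Haversine great-circle distance
#'
#' @param lat1,lon1 Origin, decimal degrees.
#' @param lat2,lon2 Destination, decimal degrees.
#' @return Distance in kilometres. Vectorised.
#' @examples
#' haversine_distance(0, 0, 1, 0) # one degree of latitude, ~111.195 km
#' @export
haversine_distance <- function(lat1, lon1, lat2, lon2) {
  .check_latlon(lat1, lon1)
  .check_latlon(lat2, lon2)
  p1 <- .deg2rad(lat1); p2 <- .deg2rad(lat2)
  dphi <- .deg2rad(lat2 - lat1)
  dlam <- .deg2rad(lon2 - lon1)
  a <- sin(dphi / 2)^2 + cos(p1) * cos(p2) * sin(dlam / 2)^2
  2 * EARTH_RADIUS_KM * asin(pmin(1, sqrt(a)))
}

#' Initial great-circle bearing
#'
#' @inheritParams haversine_distance
#' @return Bearing in degrees clockwise from geographic north, in [0, 360).
#' @export
initial_bearing <- function(lat1, lon1, lat2, lon2) {
  .check_latlon(lat1, lon1)
  .check_latlon(lat2, lon2)
  if (any(lat1 == lat2 & lon1 == lon2))
    stop("bearing undefined for identical points", call. = FALSE)
  p1 <- .deg2rad(lat1); p2 <- .deg2rad(lat2)
  dlam <- .deg2rad(lon2 - lon1)
  y <- sin(dlam) * cos(p2)
  x <- cos(p1) * sin(p2) - sin(p1) * cos(p2) * cos(dlam)
  .rad2deg(atan2(y, x)) %% 360
}

#' Destination point along a great circle
#'
#' @param lat,lon Origin, decimal degrees.
#' @param bearing Initial bearing, degrees clockwise from north.
#' @param distance_km Distance to travel, kilometres (>= 0).
#' @return List with `lat` and `lon` of the point reached.
#' @export
destination_point <- function(lat, lon, bearing, distance_km) {
  .check_latlon(lat, lon)
  if (any(!is.finite(distance_km)) || any(distance_km < 0))
    stop("distance must be nonnegative and finite", call. = FALSE)
  phi <- .deg2rad(lat); lam <- .deg2rad(lon); th <- .deg2rad(bearing)
  dr <- distance_km / EARTH_RADIUS_KM
  phi2 <- asin(sin(phi) * cos(dr) + cos(phi) * sin(dr) * cos(th))
  lam2 <- lam + atan2(sin(th) * sin(dr) * cos(phi),
                      cos(dr) - sin(phi) * sin(phi2))
  lon2 <- .rad2deg(lam2)
  lon2 <- ((lon2 + 180) %% 360) - 180
  list(lat = .rad2deg(phi2), lon = lon2)
}

#' Great-circle midpoint of two points
#'
#' @inheritParams haversine_distance
#' @return List with `lat` and `lon` of the spatial midpoint.
#' @export
great_circle_midpoint <- function(lat1, lon1, lat2, lon2) {
  .check_latlon(lat1, lon1)
  .check_latlon(lat2, lon2)
  p1 <- .deg2rad(lat1); p2 <- .deg2rad(lat2)
  dlam <- .deg2rad(lon2 - lon1)
  bx <- cos(p2) * cos(dlam)
  by <- cos(p2) * sin(dlam)
  phi_m <- atan2(sin(p1) + sin(p2), sqrt((cos(p1) + bx)^2 + by^2))
  lam_m <- .deg2rad(lon1) + atan2(by, cos(p1) + bx)
  lon_m <- ((.rad2deg(lam_m) + 180) %% 360) - 180
  list(lat = .rad2deg(phi_m), lon = lon_m)
}
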