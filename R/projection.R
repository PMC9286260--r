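# Spherical azimuthal-equidistant projection centred on the radar.
# Chosen so that distance from the radar is preserved exactly: the 9.3-km
# detection-range clip is a true disc in the planar workspace, and all
# buffer distances (1 km vicinity, 100 m boundary half-width, 246 m cells)
# are metric. Sphere radius is the IUGG mean Earth radius.

EARTH_RADIUS_M <- 6371008.8

.aeqd_fwd <- function(lon, lat, lon0, lat0) {
  lam <- deg2rad(lon); phi <- deg2rad(lat)
  lam0 <- deg2rad(lon0); phi0 <- deg2rad(lat0)
  dlam <- lam - lam0
  cosc <- sin(phi0) * sin(phi) + cos(phi0) * cos(phi) * cos(dlam)
  cosc <- pmin(1, pmax(-1, cosc))
  c <- acos(cosc)
  az <- atan2(
    sin(dlam) * cos(phi),
    cos(phi0) * sin(phi) - sin(phi0) * cos(phi) * cos(dlam)
  )
  d <- EARTH_RADIUS_M * c
  list(x = d * sin(az), y = d * cos(az))
}

.aeqd_inv <- function(x, y, lon0, lat0) {
  lam0 <- deg2rad(lon0); phi0 <- deg2rad(lat0)
  d <- sqrt(x^2 + y^2)
  c <- d / EARTH_RADIUS_M
  az <- atan2(x, y)
  phi <- asin(pmin(1, pmax(-1, sin(phi0) * cos(c) + cos(phi0) * sin(c) * cos(az))))
  lam <- lam0 + atan2(
    sin(az) * sin(c) * cos(phi0),
    cos(c) - sin(phi0) * sin(phi)
  )
  # points at the centre have undefined azimuth; the limit is the centre itself
  at0 <- d == 0
  phi[at0] <- phi0
  lam[at0] <- lam0
  list(lon = rad2deg(lam), lat = rad2deg(phi))
}

#' Project detections to the radar-centred planar workspace
#'
#' Adds planar coordinates `x`, `y` (metres east/north of the radar) using an
#' azimuthal-equidistant projection centred on the site's radar location, so
#' that distance from the radar is preserved exactly.
#'
#' @param data A data frame with `lon`, `lat` columns in WGS84 degrees.
#' @param site A [site_geometry()] object.
#' @return The input as a tibble with `x` and `y` columns appended.
#' @export
project_to_planar <- function(data, site) {
  stopifnot(is_site_geometry(site))
  data <- as_tibble(data)
  bad <- which(!is.finite(data$lon) | !is.finite(data$lat) |
                 data$lon < -180 | data$lon > 180 |
                 data$lat < -90 | data$lat > 90)
  if (length(bad) > 0) {
    abort(sprintf(
      "Out-of-range coordinates at row(s) %s.",
      paste(utils::head(bad, 5), collapse = ", ")
    ))
  }
  xy <- .aeqd_fwd(data$lon, data$lat, site$radar_lon, site$radar_lat)
  mutate(data, x = xy$x, y = xy$y)
}

#' Inverse projection from the planar workspace back to geodetic degrees
#'
#' @param data A data frame with `x`, `y` columns (metres from the radar).
#' @param site A [site_geometry()] object.
#' @return The input as a tibble with `lon` and `lat` columns replaced/added.
#' @export
planar_to_lonlat <- function(data, site) {
  stopifnot(is_site_geometry(site))
  data <- as_tibble(data)
  ll <- .aeqd_inv(data$x, data$y, site$radar_lon, site$radar_lat)
  mutate(data, lon = ll$lon, lat = ll$lat)
}
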