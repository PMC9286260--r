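#' Site geometry: radar location, detection range, and MPA polygons
#'
#' Describes one monitored site: the onshore radar position, the radius of
#' reliable detection (default 5 nautical miles = 9,260 m), one or more MPA
#' polygons (tagged no-take or limited-take), and optional exclusion polygons
#' (shoreline / obstruction masks removed from analysis). Polygons are given
#' in WGS84 geodetic coordinates; all region construction happens in the
#' radar-centred planar workspace (see [project_to_planar()]).
#'
#' @param site_id Character identifier.
#' @param radar_lon,radar_lat Radar location, WGS84 degrees.
#' @param mpa_polygons List of polygons; each polygon is a list with elements
#'   `lon`, `lat` (numeric vectors, an unclosed exterior ring) and optionally
#'   `take` (`"no_take"` or `"limited_take"`).
#' @param exclusion_polygons Optional list of polygons in the same format.
#' @param detection_range_m Detection-range radius in metres.
#' @param utc_offset_hours Signed offset from UTC defining the site's
#'   calendar days (no daylight-saving adjustment is applied).
#' @return An object of class `site_geometry`.
#' @export
site_geometry <- function(site_id, radar_lon, radar_lat, mpa_polygons,
                          exclusion_polygons = list(),
                          detection_range_m = 9260,
                          utc_offset_hours = 0) {
  if (detection_range_m <= 0) abort("`detection_range_m` must be positive.")
  if (length(mpa_polygons) == 0) abort("At least one MPA polygon is required.")
  check_poly <- function(p, what) {
    if (is.null(p$lon) || is.null(p$lat) || length(p$lon) != length(p$lat) ||
        length(p$lon) < 3) {
      abort(sprintf("Invalid %s polygon: need matching lon/lat with >= 3 vertices (repair hint: supply an unclosed exterior ring).", what))
    }
    if (.ring_self_intersects(p$lon, p$lat)) {
      abort(sprintf("Invalid %s polygon: ring self-intersects (repair hint: split it into simple polygons).", what))
    }
    p$take <- p$take %||% "no_take"
    p
  }
  mpa_polygons <- lapply(mpa_polygons, check_poly, what = "MPA")
  exclusion_polygons <- lapply(exclusion_polygons, check_poly, what = "exclusion")
  structure(
    list(
      site_id = as.character(site_id),
      radar_lon = radar_lon, radar_lat = radar_lat,
      detection_range_m = detection_range_m,
      mpa_polygons = mpa_polygons,
      exclusion_polygons = exclusion_polygons,
      utc_offset_hours = utc_offset_hours
    ),
    class = "site_geometry"
  )
}

#' @rdname site_geometry
#' @param x Object to test or print.
#' @export
is_site_geometry <- function(x) inherits(x, "site_geometry")

#' @export
print.site_geometry <- function(x, ...) {
  cat(sprintf(
    "<site_geometry> %s\n  radar: (%.5f, %.5f), range %.0f m, UTC%+g\n  MPA polygons: %d; exclusions: %d\n",
    x$site_id, x$radar_lon, x$radar_lat, x$detection_range_m,
    x$utc_offset_hours, length(x$mpa_polygons), length(x$exclusion_polygons)
  ))
  invisible(x)
}

# Segment-crossing test for ring simplicity (shared endpoints allowed).
.ring_self_intersects <- function(x, y) {
  n <- length(x)
  if (n < 4) return(FALSE)
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  seg_int <- function(i, j) {
    d <- function(ax, ay, bx, by, cx, cy) (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
    d1 <- d(x[i], y[i], x2[i], y2[i], x[j], y[j])
    d2 <- d(x[i], y[i], x2[i], y2[i], x2[j], y2[j])
    d3 <- d(x[j], y[j], x2[j], y2[j], x[i], y[i])
    d4 <- d(x[j], y[j], x2[j], y2[j], x2[i], y2[i])
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  for (i in seq_len(n - 2)) {
    for (j in (i + 2):n) {
      if (i == 1 && j == n) next  # adjacent around the ring
      if (seg_int(i, j)) return(TRUE)
    }
  }
  FALSE
}

# MPA union in planar coordinates.
.site_mpa_planar <- function(site) {
  polys <- lapply(site$mpa_polygons, function(p) {
    xy <- .aeqd_fwd(p$lon, p$lat, site$radar_lon, site$radar_lat)
    list(list(x = xy$x, y = xy$y))
  })
  poly_union_all(polys)
}

.site_exclusions_planar <- function(site) {
  polys <- lapply(site$exclusion_polygons, function(p) {
    xy <- .aeqd_fwd(p$lon, p$lat, site$radar_lon, site$radar_lat)
    list(list(x = xy$x, y = xy$y))
  })
  poly_union_all(polys)
}

#' Read and write site geometry as GeoJSON
#'
#' The site file is a WGS84 GeoJSON `FeatureCollection`: one `Point` feature
#' with properties `role: "radar"`, `site_id`, `detection_range_m` and
#' `utc_offset_hours`; one or more `Polygon` features with `role: "mpa"`
#' (optional `take` property) and any number with `role: "exclusion"`.
#'
#' @param path File path.
#' @return `read_site_geojson()` returns a [site_geometry()];
#'   `write_site_geojson()` returns `path` invisibly.
#' @export
read_site_geojson <- function(path) {
  g <- jsonlite::read_json(path)
  if (is.null(g$features)) abort("Not a GeoJSON FeatureCollection.")
  radar <- NULL; mpas <- list(); excl <- list()
  for (f in g$features) {
    role <- f$properties$role %||% ""
    if (role == "radar") {
      radar <- f
    } else if (role %in% c("mpa", "exclusion")) {
      ring <- f$geometry$coordinates[[1]]
      lon <- vapply(ring, function(c) c[[1]], numeric(1))
      lat <- vapply(ring, function(c) c[[2]], numeric(1))
      n <- length(lon)
      if (lon[1] == lon[n] && lat[1] == lat[n]) { lon <- lon[-n]; lat <- lat[-n] }
      poly <- list(lon = lon, lat = lat, take = f$properties$take %||% "no_take")
      if (role == "mpa") mpas <- c(mpas, list(poly)) else excl <- c(excl, list(poly))
    }
  }
  if (is.null(radar)) abort("Site GeoJSON has no feature with role 'radar'.")
  site_geometry(
    site_id = radar$properties$site_id %||% "site",
    radar_lon = radar$geometry$coordinates[[1]],
    radar_lat = radar$geometry$coordinates[[2]],
    mpa_polygons = mpas,
    exclusion_polygons = excl,
    detection_range_m = radar$properties$detection_range_m %||% 9260,
    utc_offset_hours = radar$properties$utc_offset_hours %||% 0
  )
}

#' @rdname read_site_geojson
#' @param site A [site_geometry()] object.
#' @export
write_site_geojson <- function(site, path) {
  stopifnot(is_site_geometry(site))
  close_ring <- function(lon, lat) {
    lapply(c(seq_along(lon), 1L), function(i) c(lon[i], lat[i]))
  }
  feats <- list(list(
    type = "Feature",
    geometry = list(type = "Point",
                    coordinates = c(site$radar_lon, site$radar_lat)),
    properties = list(role = "radar", site_id = site$site_id,
                      detection_range_m = site$detection_range_m,
                      utc_offset_hours = site$utc_offset_hours)
  ))
  add_polys <- function(polys, role) {
    lapply(polys, function(p) list(
      type = "Feature",
      geometry = list(type = "Polygon",
                      coordinates = list(close_ring(p$lon, p$lat))),
      properties = list(role = role, take = p$take %||% "no_take")
    ))
  }
  feats <- c(feats, add_polys(site$mpa_polygons, "mpa"),
             add_polys(site$exclusion_polygons, "exclusion"))
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
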