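#' Sunrise and sunset times from solar position
#'
#' NOAA solar-position equations (geometric mean longitude/anomaly, equation
#' of time, solar declination, hour angle at zenith 90.833 degrees to
#' include refraction and the solar disc). Accurate to within about two
#' minutes at mid-latitudes; polar day/night latitudes are rejected.
#'
#' @param date `Date` vector.
#' @param lat,lon Site latitude/longitude, WGS84 degrees.
#' @param utc_offset_hours Local offset from UTC in hours.
#' @return Tibble with `date`, `sunrise`, `sunset` — local-clock `POSIXct`
#'   instants (represented in UTC with the offset already applied).
#' @export
sun_times <- function(date, lat, lon, utc_offset_hours = 0) {
  if (abs(lat) >= 66) abort("Latitudes beyond +/-66 degrees are out of scope (polar day/night).")
  date <- as.Date(date)
  # Julian century at local solar noon
  jd <- as.numeric(date) + 2440587.5 + 0.5 - lon / 360 - utc_offset_hours / 24
  t <- (jd - 2451545) / 36525

  L0 <- (280.46646 + t * (36000.76983 + 0.0003032 * t)) %% 360
  M <- 357.52911 + t * (35999.05029 - 0.0001537 * t)
  e <- 0.016708634 - t * (0.000042037 + 0.0000001267 * t)
  C <- sin(deg2rad(M)) * (1.914602 - t * (0.004817 + 0.000014 * t)) +
    sin(deg2rad(2 * M)) * (0.019993 - 0.000101 * t) +
    sin(deg2rad(3 * M)) * 0.000289
  true_long <- L0 + C
  omega <- 125.04 - 1934.136 * t
  lambda <- true_long - 0.00569 - 0.00478 * sin(deg2rad(omega))
  eps0 <- 23 + (26 + (21.448 - t * (46.815 + t * (0.00059 - 0.001813 * t))) / 60) / 60
  eps <- eps0 + 0.00256 * cos(deg2rad(omega))
  decl <- asin(sin(deg2rad(eps)) * sin(deg2rad(lambda)))

  y <- tan(deg2rad(eps / 2))^2
  eqtime <- 4 * rad2deg(
    y * sin(2 * deg2rad(L0)) - 2 * e * sin(deg2rad(M)) +
      4 * e * y * sin(deg2rad(M)) * cos(2 * deg2rad(L0)) -
      0.5 * y^2 * sin(4 * deg2rad(L0)) - 1.25 * e^2 * sin(2 * deg2rad(M))
  )

  phi <- deg2rad(lat)
  cosH <- cos(deg2rad(90.833)) / (cos(phi) * cos(decl)) - tan(phi) * tan(decl)
  if (any(abs(cosH) > 1)) abort("Sun does not rise/set on the given date(s) at this latitude.")
  H <- rad2deg(acos(cosH))

  noon_min <- 720 - 4 * lon - eqtime + utc_offset_hours * 60
  rise_min <- noon_min - 4 * H
  set_min <- noon_min + 4 * H
  base <- as.POSIXct(paste(date, "00:00:00"), tz = "UTC")
  tibble(date = date,
         sunrise = base + rise_min * 60,
         sunset = base + set_min * 60)
}
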