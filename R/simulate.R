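# Synthetic radar-track generator: behaviour archetypes with ground-truth
# labels, day-level count variability, sea-clutter false tracks and
# maintenance gaps, so every pipeline stage is testable without radar data.

#' Vessel behaviour archetypes
#'
#' Kinematic parameter sets placed firmly inside (or outside) the
#' classification thresholds so closed-loop recovery tests probe the
#' pipeline rather than marginal cases: `transit` (> 6 kn, near-straight),
#' `focal_loiter` (< 1.8 kn, large turn noise), `linear_tow` (2.5–4.5 kn,
#' per-step turn noise far below 15° per window, speed jitter far below
#' 25%), and `clutter` (short, erratic, near-zero net displacement).
#'
#' @param name Archetype name.
#' @return A list of kinematic parameters (speeds in knots, turn noise in
#'   degrees per step, duration range in seconds, measurement noise for
#'   the recorded speed/heading).
#' @export
archetype <- function(name = c("transit", "focal_loiter", "linear_tow", "clutter")) {
  name <- match.arg(name)
  switch(name,
    transit = list(name = "transit", speed_mean = 9, speed_sd = 0.4,
                   speed_range = c(6.5, 14), turn_sd = 0.5,
                   duration_range = c(600, 1500),
                   obs_sog_sd = 0.1, obs_heading_sd = 2),
    focal_loiter = list(name = "focal_loiter", speed_mean = 1.0, speed_sd = 0.25,
                        speed_range = c(0.55, 1.7), turn_sd = 40,
                        duration_range = c(600, 3000),
                        obs_sog_sd = 0.05, obs_heading_sd = 5),
    linear_tow = list(name = "linear_tow", speed_mean = 3.5, speed_sd = 0.1,
                      speed_range = c(2.5, 4.5), turn_sd = 1,
                      duration_range = c(900, 3000),
                      obs_sog_sd = 0.05, obs_heading_sd = 1.5),
    clutter = list(name = "clutter", speed_mean = 0.3, speed_sd = 0.3,
                   speed_range = c(0, 1.5), turn_sd = 120,
                   duration_range = c(4, 18),
                   obs_sog_sd = 0.1, obs_heading_sd = 30)
  )
}

#' Simulate one labelled vessel track
#'
#' Correlated random walk: heading evolves by persistence plus Gaussian
#' turn noise, speed follows an AR(1) pull toward the archetype mean
#' (clamped to the archetype range), position integrates speed over the
#' sampling interval, and Gaussian positional jitter is added after
#' integration. The recorded speed over ground and heading are the
#' kinematic values plus measurement noise. Every point carries its
#' ground-truth archetype label.
#'
#' @param arch An [archetype()].
#' @param start_xy Planar start position (metres from the radar).
#' @param start_time `POSIXct` UTC start instant.
#' @param track_id Identifier.
#' @param duration_s Track duration; default drawn from the archetype range.
#' @param interval_s Sampling interval (default 2 s).
#' @param noise_sd_m Positional jitter standard deviation (default 5 m).
#' @param noiseless Zero out positional and measurement noise (ground-truth
#'   recovery tests).
#' @param heading0 Initial heading; default uniform.
#' @return Detection tibble with planar `x`, `y` and a `truth` column.
#' @export
simulate_track <- function(arch, start_xy, start_time, track_id,
                           duration_s = NULL, interval_s = 2,
                           noise_sd_m = 5, noiseless = FALSE,
                           heading0 = NULL) {
  duration_s <- duration_s %||% stats::runif(1, arch$duration_range[1],
                                             arch$duration_range[2])
  n <- max(2, floor(duration_s / interval_s) + 1)
  heading0 <- heading0 %||% stats::runif(1, 0, 360)
  obs_sog_sd <- if (noiseless) 0 else arch$obs_sog_sd
  obs_heading_sd <- if (noiseless) 0 else arch$obs_heading_sd
  pos_sd <- if (noiseless) 0 else noise_sd_m

  turn <- stats::rnorm(n, 0, arch$turn_sd)
  heading <- (heading0 + cumsum(c(0, turn[-1]))) %% 360
  speed <- numeric(n)
  speed[1] <- min(max(stats::rnorm(1, arch$speed_mean, arch$speed_sd),
                      arch$speed_range[1]), arch$speed_range[2])
  phi <- 0.8
  innov_sd <- arch$speed_sd * sqrt(1 - phi^2)
  for (i in seq_len(n - 1)) {
    s <- arch$speed_mean + phi * (speed[i] - arch$speed_mean) +
      stats::rnorm(1, 0, innov_sd)
    speed[i + 1] <- min(max(s, arch$speed_range[1]), arch$speed_range[2])
  }
  v <- knots_to_mps(speed)
  dx <- v * interval_s * sin(deg2rad(heading))
  dy <- v * interval_s * cos(deg2rad(heading))
  x <- start_xy[1] + cumsum(c(0, dx[-n]))
  y <- start_xy[2] + cumsum(c(0, dy[-n]))
  tibble(
    track_id = track_id,
    timestamp = start_time + (seq_len(n) - 1) * interval_s,
    x = x + stats::rnorm(n, 0, pos_sd),
    y = y + stats::rnorm(n, 0, pos_sd),
    sog_kn = pmax(0, speed + stats::rnorm(n, 0, obs_sog_sd)),
    heading_deg = (heading + stats::rnorm(n, 0, obs_heading_sd)) %% 360,
    truth = arch$name
  )
}

#' Demonstration site fixture
#'
#' A rectangular no-take MPA (4 km x 4 km by default) offshore of a radar
#' at a central-California-like location, 9,260-m detection range, no
#' exclusion masks, Pacific standard time.
#'
#' @param site_id Identifier.
#' @param mpa_planar Planar MPA rectangle `c(xmin, ymin, xmax, ymax)` in
#'   metres from the radar.
#' @param utc_offset_hours Site UTC offset.
#' @return A [site_geometry()].
#' @export
demo_site <- function(site_id = "demo",
                      mpa_planar = c(-3000, 2000, 1000, 6000),
                      utc_offset_hours = -8) {
  radar_lon <- -120.6; radar_lat <- 34.45
  corners <- list(
    x = c(mpa_planar[1], mpa_planar[3], mpa_planar[3], mpa_planar[1]),
    y = c(mpa_planar[2], mpa_planar[2], mpa_planar[4], mpa_planar[4])
  )
  ll <- .aeqd_inv(corners$x, corners$y, radar_lon, radar_lat)
  site_geometry(
    site_id = site_id, radar_lon = radar_lon, radar_lat = radar_lat,
    mpa_polygons = list(list(lon = ll$lon, lat = ll$lat, take = "no_take")),
    detection_range_m = 9260,
    utc_offset_hours = utc_offset_hours
  )
}

#' Scenario definition for the synthetic generator
#'
#' Bundles the study conditions for a simulated deployment: the site, the
#' date range, mean daily track intensity per archetype, a log-normal
#' day-level count multiplier (so the 2-SD log-count day filter has real
#' work to do), a sea-clutter rate, positional noise, the 2-s sampling
#' interval, maintenance days, optional boundary bias for focal starts
#' ("fishing the line"), optional season calendar with an open-season
#' intensity multiplier, and the RNG seed. Fully reproducible from the
#' seed.
#'
#' @param site A [site_geometry()].
#' @param start_date First day.
#' @param n_days Number of days.
#' @param daily_intensity Named mean tracks/day by archetype.
#' @param day_effect_sd SD of the log-normal day multiplier.
#' @param clutter_rate Mean clutter tracks/day.
#' @param noise_sd_m Positional jitter SD, metres.
#' @param interval_s Sampling interval, seconds.
#' @param maintenance_days `Date` vector.
#' @param boundary_bias Non-negative weight concentrating focal starts in
#'   the boundary band (0 = uniform over the vicinity).
#' @param calendar Optional [season_calendar()].
#' @param open_season_multiplier Intensity multiplier for pattern-matched
#'   archetypes on open days.
#' @param seed Integer RNG seed.
#' @return A `scenario` list object.
#' @export
scenario <- function(site = demo_site(),
                     start_date = as.Date("2019-01-01"),
                     n_days = 30,
                     daily_intensity = c(transit = 6, focal_loiter = 3,
                                         linear_tow = 3),
                     day_effect_sd = 0.5,
                     clutter_rate = 4,
                     noise_sd_m = 5,
                     interval_s = 2,
                     maintenance_days = as.Date(character()),
                     boundary_bias = 0,
                     calendar = NULL,
                     open_season_multiplier = 2,
                     seed = 1) {
  structure(
    list(site = site, start_date = as.Date(start_date), n_days = n_days,
         daily_intensity = daily_intensity, day_effect_sd = day_effect_sd,
         clutter_rate = clutter_rate, noise_sd_m = noise_sd_m,
         interval_s = interval_s,
         maintenance_days = as.Date(maintenance_days),
         boundary_bias = boundary_bias, calendar = calendar,
         open_season_multiplier = open_season_multiplier, seed = seed),
    class = "scenario"
  )
}

#' Bias a scenario's focal activity toward the MPA boundary
#'
#' Returns the scenario with focal-loiter start points drawn preferentially
#' within the boundary band, emulating "fishing the line". With positive
#' bias, expected boundary-region hours per km² exceed inner-region hours
#' per km².
#'
#' @param scn A [scenario()].
#' @param boundary_bias Non-negative; the probability a focal start is
#'   placed in the boundary band is `bias / (1 + bias)`, the remainder
#'   uniform over the vicinity.
#' @return The modified scenario.
#' @export
make_fishing_the_line_scenario <- function(scn, boundary_bias) {
  stopifnot(inherits(scn, "scenario"), boundary_bias >= 0)
  scn$boundary_bias <- boundary_bias
  scn
}

# uniform sample inside a planar polygon by bbox rejection
sample_in_poly <- function(p, n) {
  bb <- poly_bbox(p)
  xs <- numeric(0); ys <- numeric(0)
  while (length(xs) < n) {
    m <- max(2 * (n - length(xs)), 16)
    cx <- stats::runif(m, bb["xmin"], bb["xmax"])
    cy <- stats::runif(m, bb["ymin"], bb["ymax"])
    ok <- points_in_poly(cx, cy, p)
    xs <- c(xs, cx[ok]); ys <- c(ys, cy[ok])
  }
  cbind(xs[seq_len(n)], ys[seq_len(n)])
}

#' Simulate a full monitoring scenario
#'
#' Draws daily track counts per archetype (Poisson intensity modulated by a
#' log-normal day effect and, when a calendar is given, by the open-season
#' multiplier for the matching pattern), simulates each track with
#' [simulate_track()], injects clutter tracks and emits tracks on
#' maintenance days so the exclusion filters can be exercised. All outputs
#' are reproducible from the scenario seed.
#'
#' @param scn A [scenario()].
#' @return A list: `detections` (ingest dialect, with lon/lat), `truth`
#'   (per-point archetype labels), `site`, `regions`, `maintenance_days`,
#'   `calendar`, `scenario`.
#' @export
simulate_scenario <- function(scn) {
  stopifnot(inherits(scn, "scenario"))
  set.seed(scn$seed)
  site <- scn$site
  regions <- build_regions(site)
  vic <- regions$polys$vicinity
  band <- regions$polys$boundary
  rng_poly <- regions$polys$full_range

  days <- scn$start_date + seq_len(scn$n_days) - 1
  all_tracks <- list()
  tid <- 0
  for (d in seq_along(days)) {
    day <- days[d]
    day_mult <- exp(stats::rnorm(1, 0, scn$day_effect_sd))
    day_start_utc <- as.POSIXct(paste(day, "00:00:00"), tz = "UTC") -
      site$utc_offset_hours * 3600
    for (an in names(scn$daily_intensity)) {
      arch <- archetype(an)
      lambda <- scn$daily_intensity[[an]] * day_mult
      if (!is.null(scn$calendar)) {
        open_any <- vapply(scn$calendar$fisheries$fishery_id, function(fid) {
          i <- match(fid, scn$calendar$fisheries$fishery_id)
          pat <- scn$calendar$fisheries$pattern[i]
          matches <- (pat == "focal" && an == "focal_loiter") ||
            (pat == "linear" && an == "linear_tow") ||
            (pat == "both" && an %in% c("focal_loiter", "linear_tow"))
          matches && season_state(day, scn$calendar, fid) == "open"
        }, logical(1))
        if (any(open_any)) lambda <- lambda * scn$open_season_multiplier
      }
      n_tracks <- stats::rpois(1, lambda)
      if (n_tracks == 0) next
      for (k in seq_len(n_tracks)) {
        tid <- tid + 1
        start_time <- day_start_utc + stats::runif(1, 0, 86400 - 1)
        if (an == "focal_loiter" && scn$boundary_bias > 0 &&
            stats::runif(1) < scn$boundary_bias / (1 + scn$boundary_bias)) {
          start_xy <- sample_in_poly(band, 1)
        } else if (an %in% c("focal_loiter", "linear_tow")) {
          start_xy <- sample_in_poly(vic, 1)
        } else {
          start_xy <- sample_in_poly(rng_poly, 1)
        }
        all_tracks[[tid]] <- simulate_track(
          arch, start_xy[1, ], start_time,
          track_id = sprintf("T%06d", tid),
          interval_s = scn$interval_s, noise_sd_m = scn$noise_sd_m)
      }
    }
    # sea clutter
    n_clut <- stats::rpois(1, scn$clutter_rate)
    for (k in seq_len(n_clut)) {
      tid <- tid + 1
      start_time <- day_start_utc + stats::runif(1, 0, 86400 - 1)
      start_xy <- sample_in_poly(rng_poly, 1)
      all_tracks[[tid]] <- simulate_track(
        archetype("clutter"), start_xy[1, ], start_time,
        track_id = sprintf("T%06d", tid),
        interval_s = scn$interval_s, noise_sd_m = scn$noise_sd_m)
    }
  }
  det <- bind_rows(all_tracks)
  det <- planar_to_lonlat(det, site)
  truth <- det |>
    group_by(.data$track_id) |>
    mutate(point_index = row_number()) |>
    ungroup() |>
    select("track_id", "point_index", archetype = "truth")
  detections <- det |>
    select("track_id", "timestamp", "lon", "lat", "sog_kn", "heading_deg")
  list(detections = detections, truth = truth, site = site,
       regions = regions, maintenance_days = scn$maintenance_days,
       calendar = scn$calendar, scenario = scn)
}

#' Write a simulated scenario to disk
#'
#' Emits the fixture bundle: detection CSV (ingest dialect), truth CSV,
#' site GeoJSON, and — when the scenario has a calendar — the season
#' calendar YAML.
#'
#' @param sim Result of [simulate_scenario()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_detections(sim$detections, file.path(dir, "detections.csv"))
  readr::write_csv(sim$truth, file.path(dir, "truth.csv"), progress = FALSE)
  write_site_geojson(sim$site, file.path(dir, "site.geojson"))
  if (!is.null(sim$calendar)) {
    write_season_calendar(sim$calendar, file.path(dir, "calendar.yaml"))
  }
  if (length(sim$maintenance_days) > 0) {
    readr::write_csv(tibble(maintenance_day = sim$maintenance_days),
                     file.path(dir, "maintenance_days.csv"), progress = FALSE)
  }
  invisible(dir)
}
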