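suppressPackageStartupMessages({
  library(dplyr)
  library(tibble)
})

# Square-MPA site used throughout: 4 km x 4 km MPA fully inside the range.
square_site <- function() demo_site(site_id = "sq")

square_regions <- function() build_regions(square_site())

# A detection tibble from explicit per-point vectors (planar coordinates are
# unprojected around the site's radar so lon/lat stay consistent).
make_track <- function(track_id, x, y, sog_kn, heading_deg,
                       t0 = as.POSIXct("2019-06-01 18:00:00", tz = "UTC"),
                       dt = 2, site = square_site()) {
  n <- length(x)
  ll <- mpatrack:::.aeqd_inv(x, y, site$radar_lon, site$radar_lat)
  tibble(
    track_id = track_id,
    timestamp = t0 + (seq_len(n) - 1) * dt,
    lon = ll$lon, lat = ll$lat,
    sog_kn = rep_len(sog_kn, n), heading_deg = rep_len(heading_deg, n),
    x = x, y = y
  )
}

# Straight constant-speed track starting at (x0, y0), heading in degrees
# clockwise from north.
straight_track <- function(track_id, n, sog_kn, heading_deg,
                           x0 = 0, y0 = 3000, dt = 2, ...) {
  v <- sog_kn * 1852 / 3600
  x <- x0 + (seq_len(n) - 1) * v * dt * sin(heading_deg * pi / 180)
  y <- y0 + (seq_len(n) - 1) * v * dt * cos(heading_deg * pi / 180)
  make_track(track_id, x, y, sog_kn, heading_deg, dt = dt, ...)
}

# Brute-force per-point behaviour labels: recompute the window statistics
# from scratch for every point, independent of the vectorised implementation.
brute_force_labels <- function(det, k = 12, speed_band = c(2, 6),
                               turn_thresh = 15, speed_dev_thresh = 0.25) {
  det <- det[order(det$track_id, det$timestamp), ]
  out <- character(nrow(det))
  for (tid in unique(det$track_id)) {
    idx <- which(det$track_id == tid)
    sog <- det$sog_kn[idx]; hdg <- det$heading_deg[idx]
    for (j in seq_along(idx)) {
      lab <- "other"
      full <- j > k
      if (full) {
        w <- (j - k):(j - 1)
        ms <- mean(sog[w])
        th <- hdg[w] * pi / 180
        mh <- atan2(mean(sin(th)), mean(cos(th))) * 180 / pi
        dv <- abs(hdg[j] - mh) %% 360
        if (dv > 180) dv <- 360 - dv
        rel <- if (ms > 0) abs(sog[j] - ms) / ms else Inf
        if (sog[j] >= speed_band[1] && sog[j] <= speed_band[2]) {
          if (dv >= turn_thresh) lab <- "focal"
          else if (rel < speed_dev_thresh) lab <- "linear"
        }
      }
      if (sog[j] < speed_band[1]) lab <- "focal"
      out[idx[j]] <- lab
    }
  }
  out
}

# Exhaustive permutation oracle for the exact quantile test: enumerate every
# assignment of m of the N pooled values to the first sample and count
# assignments at least as extreme as observed (same pooled-quantile
# convention as the implementation, recomputed independently).
permutation_quantile_p <- function(x, y, q = 0.5,
                                   alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  pooled <- c(x, y)
  N <- length(pooled); m <- length(x)
  xi <- sort(pooled)[ceiling(q * N)]
  a_obs <- sum(x <= xi)
  combos <- utils::combn(N, m)
  a_all <- apply(combos, 2, function(ii) sum(pooled[ii] <= xi))
  if (alternative == "greater") mean(a_all >= a_obs) else mean(a_all <= a_obs)
}

# Random star-shaped simple polygon (lon/lat) around a planar centre.
random_star_mpa <- function(site, centre = c(-1000, 3500), n_vertices = 8,
                            r_min = 800, r_max = 2500) {
  th <- sort(runif(n_vertices, 0, 2 * pi))
  r <- runif(n_vertices, r_min, r_max)
  x <- centre[1] + r * cos(th)
  y <- centre[2] + r * sin(th)
  ll <- mpatrack:::.aeqd_inv(x, y, site$radar_lon, site$radar_lat)
  list(lon = ll$lon, lat = ll$lat)
}
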