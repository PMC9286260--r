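#' Rolling-window kinematic features for behaviour classification
#'
#' For each detection point, summarises the preceding `k` points of the same
#' track (excluding the current point): mean speed, circular mean heading
#' (unit-vector average, so the average is correct across north), the
#' wrapped absolute deviation of the current heading from that mean
#' (`heading_dev`, in [0, 180]) and the relative speed deviation
#' `|sog - mean| / mean` (`Inf` when the preceding mean speed is zero).
#' `window_full` marks points with a complete preceding window; earlier
#' points keep features over the shorter available window but are never
#' eligible for the windowed rules.
#'
#' @param detections Detection tibble (`track_id`, `timestamp`, `sog_kn`,
#'   `heading_deg`).
#' @param k Window length in points (default 12).
#' @return The input, time-ordered within track, with `point_index`,
#'   `mean_speed_prev`, `heading_dev`, `rel_speed_dev`, `window_full`.
#' @export
window_features <- function(detections, k = 12) {
  detections |>
    group_by(.data$track_id) |>
    arrange(.data$timestamp, .by_group = TRUE) |>
    mutate(point_index = row_number()) |>
    mutate(.window_feats(.data$sog_kn, .data$heading_deg, k)) |>
    ungroup()
}

.window_feats <- function(sog, heading, k) {
  n <- length(sog)
  cs_speed <- c(0, cumsum(sog))
  cs_sin <- c(0, cumsum(sin(deg2rad(heading))))
  cs_cos <- c(0, cumsum(cos(deg2rad(heading))))
  i <- seq_len(n)
  lo <- pmax(i - k, 1)       # window = points lo .. i-1
  m <- i - lo
  mean_speed <- ifelse(m > 0, (cs_speed[i] - cs_speed[lo]) / m, NA_real_)
  sbar <- ifelse(m > 0, (cs_sin[i] - cs_sin[lo]) / m, NA_real_)
  cbar <- ifelse(m > 0, (cs_cos[i] - cs_cos[lo]) / m, NA_real_)
  mean_heading <- (rad2deg(atan2(sbar, cbar))) %% 360
  heading_dev <- angle_diff(heading, mean_heading)
  heading_dev[m == 0] <- NA_real_
  rel_dev <- ifelse(m > 0 & mean_speed > 0,
                    abs(sog - mean_speed) / mean_speed,
                    ifelse(m > 0, Inf, NA_real_))
  tibble(
    mean_speed_prev = mean_speed,
    circ_mean_heading_prev = mean_heading,
    heading_dev = heading_dev,
    rel_speed_dev = rel_dev,
    window_full = i > k
  )
}

#' Label detection points focal, linear, or other
#'
#' Applies the activity-of-interest heuristics at each point, in fixed
#' order: (a) speed below the slow band (< 2 kn) is focal regardless of the
#' window; (b) speed within the 2–6 kn band with a full window and heading
#' deviating >= 15 degrees from the preceding average is focal; (c) speed in
#' band, full window, heading deviation < 15 degrees and speed within 25% of
#' the preceding average is linear; (d) anything else (including transit at
#' > 6 kn and points without a full window) is other. Focal and linear are
#' mutually exclusive by construction.
#'
#' @param detections Output of [window_features()].
#' @param speed_band Length-2 inclusive speed band in knots.
#' @param turn_thresh Heading-deviation threshold, degrees.
#' @param speed_dev_thresh Relative speed-deviation threshold.
#' @return The input with a `behavior_raw` factor
#'   (`focal`/`linear`/`other`).
#' @export
classify_points <- function(detections, speed_band = c(2, 6),
                            turn_thresh = 15, speed_dev_thresh = 0.25) {
  sog <- detections$sog_kn
  in_band <- sog >= speed_band[1] & sog <= speed_band[2]
  wf <- detections$window_full
  dev <- detections$heading_dev
  rel <- detections$rel_speed_dev
  lab <- rep("other", nrow(detections))
  lab[in_band & wf & !is.na(dev) & dev >= turn_thresh] <- "focal"
  lab[in_band & wf & !is.na(dev) & dev < turn_thresh &
        !is.na(rel) & rel < speed_dev_thresh] <- "linear"
  lab[sog < speed_band[1]] <- "focal"   # rule (a) wins regardless of window
  mutate(detections,
         behavior_raw = factor(lab, levels = c("focal", "linear", "other")))
}

#' Extract qualifying activity segments
#'
#' Maximal runs of identically labelled focal or linear points with at
#' least `min_run` points become activity segments; shorter runs do not
#' qualify (their points are demoted to `other` downstream). Runs of
#' `other` never form segments.
#'
#' @param detections Output of [classify_points()] (needs `track_id`,
#'   `point_index`, `timestamp`, `behavior_raw`).
#' @param min_run Minimum run length in points (default 12).
#' @return Segments tibble: `segment_id`, `track_id`, `label`,
#'   `start_index`, `end_index`, `start_time`, `end_time`, `n_points`.
#' @export
extract_segments <- function(detections, min_run = 12) {
  det <- detections |>
    arrange(.data$track_id, .data$point_index)
  segs <- det |>
    group_by(.data$track_id) |>
    dplyr::group_modify(function(d, key) {
      r <- rle(as.character(d$behavior_raw))
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      ok <- r$values %in% c("focal", "linear") & r$lengths >= min_run
      tibble(
        label = r$values[ok],
        start_index = d$point_index[starts[ok]],
        end_index = d$point_index[ends[ok]],
        start_time = d$timestamp[starts[ok]],
        end_time = d$timestamp[ends[ok]],
        n_points = r$lengths[ok]
      )
    }) |>
    ungroup()
  mutate(segs, segment_id = row_number()) |>
    select("segment_id", dplyr::everything())
}

#' Full behaviour classification of detection points
#'
#' Convenience wrapper: rolling-window features, point rules, and the
#' minimum-run segment filter. Points inside a qualifying segment keep
#' their focal/linear label in `behavior`; all other points are `other`.
#'
#' @inheritParams window_features
#' @inheritParams classify_points
#' @inheritParams extract_segments
#' @return The detections with feature columns, `behavior_raw`, final
#'   `behavior`, and `segment_id` (NA outside segments). The segments
#'   tibble is attached as attribute `"segments"` and retrievable with
#'   [activity_segments()].
#' @export
classify_behavior <- function(detections, k = 12, speed_band = c(2, 6),
                              turn_thresh = 15, speed_dev_thresh = 0.25,
                              min_run = 12) {
  det <- detections |>
    window_features(k = k) |>
    classify_points(speed_band = speed_band, turn_thresh = turn_thresh,
                    speed_dev_thresh = speed_dev_thresh)
  segs <- extract_segments(det, min_run = min_run)
  det <- det |>
    mutate(behavior = factor("other", levels = c("focal", "linear", "other")),
           segment_id = NA_integer_)
  if (nrow(segs) > 0) {
    for (s in seq_len(nrow(segs))) {
      sel <- det$track_id == segs$track_id[s] &
        det$point_index >= segs$start_index[s] &
        det$point_index <= segs$end_index[s]
      det$behavior[sel] <- segs$label[s]
      det$segment_id[sel] <- segs$segment_id[s]
    }
  }
  attr(det, "segments") <- segs
  det
}

#' @rdname classify_behavior
#' @param classified Result of `classify_behavior()`.
#' @export
activity_segments <- function(classified) {
  attr(classified, "segments") %||%
    abort("No segments attribute; run classify_behavior() first.")
}
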