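#' Per-track kinematic summary features
#'
#' Computes the feature set used for false-target screening: duration,
#' point count, median speed over ground, net displacement, straightness
#' (net displacement / cumulative path length) and mean absolute turn
#' between successive headings.
#'
#' @param detections Detection tibble with planar `x`, `y`.
#' @return One row per track: `track_id`, `n_points`, `duration_s`,
#'   `median_sog_kn`, `net_displacement_m`, `path_length_m`,
#'   `straightness`, `mean_abs_turn_deg`.
#' @export
track_features <- function(detections) {
  detections |>
    group_by(.data$track_id) |>
    arrange(.data$timestamp, .by_group = TRUE) |>
    summarise(
      n_points = n(),
      duration_s = as.numeric(difftime(max(.data$timestamp),
                                       min(.data$timestamp), units = "secs")),
      median_sog_kn = stats::median(.data$sog_kn),
      net_displacement_m = sqrt((dplyr::last(.data$x) - dplyr::first(.data$x))^2 +
                                  (dplyr::last(.data$y) - dplyr::first(.data$y))^2),
      path_length_m = sum(sqrt(diff(.data$x)^2 + diff(.data$y)^2)),
      mean_abs_turn_deg = if (n() >= 3) {
        mean(angle_diff(.data$heading_deg[-1], .data$heading_deg[-n()]))
      } else NA_real_,
      .groups = "drop"
    ) |>
    mutate(straightness = ifelse(.data$path_length_m > 0,
                                 .data$net_displacement_m / .data$path_length_m,
                                 0))
}

#' Rule-based false-target screener
#'
#' Returns a screener function (features tibble in, label vector out)
#' implementing the default surrogate rule: a track is a `false_target` iff
#' it has fewer than `min_points` points, or lasts less than
#' `min_duration_s` seconds, or is both highly tortuous
#' (straightness < `max_still_straightness`) and essentially stationary
#' (median speed < `max_still_sog_kn`). Sea-clutter returns are short,
#' erratic and have near-zero net displacement, which these rules target.
#'
#' @param min_points,min_duration_s,max_still_straightness,max_still_sog_kn
#'   Rule thresholds.
#' @return A function usable as the `screener` argument of
#'   [screen_false_targets()].
#' @export
rule_screener <- function(min_points = 12, min_duration_s = 30,
                          max_still_straightness = 0.05,
                          max_still_sog_kn = 0.5) {
  function(features) {
    ifelse(
      features$n_points < min_points |
        features$duration_s < min_duration_s |
        (features$straightness < max_still_straightness &
           features$median_sog_kn < max_still_sog_kn),
      "false_target", "vessel"
    )
  }
}

#' Screen tracks for radar false targets
#'
#' Labels every track `vessel` or `false_target` using a pluggable
#' screener over [track_features()]. Single-point tracks are labelled
#' `false_target` directly (no kinematics to evaluate). If the screener
#' errors on the feature set, affected tracks are labelled `vessel` and
#' flagged — failing open so true vessels are not silently lost.
#'
#' @param detections Detection tibble with planar `x`, `y`.
#' @param screener Function mapping a [track_features()] tibble to a
#'   character vector of labels; default [rule_screener()].
#' @return One row per track: `track_id`, `label`, `screener_failed`,
#'   joined to its features.
#' @export
screen_false_targets <- function(detections, screener = rule_screener()) {
  feats <- track_features(detections)
  lab <- rep("vessel", nrow(feats))
  failed <- rep(FALSE, nrow(feats))
  res <- tryCatch(screener(feats), error = function(e) e)
  if (inherits(res, "error") || length(res) != nrow(feats) || anyNA(res)) {
    failed <- rep(TRUE, nrow(feats))
    warn("Screener failed; all tracks labelled 'vessel' and flagged.")
  } else {
    lab <- as.character(res)
  }
  lab[feats$n_points < 2] <- "false_target"
  failed[feats$n_points < 2] <- FALSE
  feats |>
    mutate(label = lab, screener_failed = failed) |>
    select("track_id", "label", "screener_failed", dplyr::everything())
}

#' Drop tracks labelled as false targets
#'
#' @param detections Detection tibble.
#' @param screen_result Result of [screen_false_targets()].
#' @return Detections restricted to tracks labelled `vessel`.
#' @export
remove_false_targets <- function(detections, screen_result) {
  keep <- screen_result$track_id[screen_result$label == "vessel"]
  out <- detections[detections$track_id %in% keep, ]
  attr(out, "n_removed_tracks") <-
    sum(screen_result$label == "false_target")
  out
}
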