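#' @importFrom rlang %||% .data abort warn inform
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   left_join bind_rows distinct n row_number across all_of rename count
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom purrr map map_dbl map_lgl map_chr imap pmap keep
NULL

# Round half away from zero to `digits` (printed-table convention for
# percentages; base round() is banker's rounding).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Integer percentage of a total, rounded half away from zero
#'
#' Convenience used by the summary tables: `100 * x / total` rounded to the
#' nearest whole percent, ties away from zero.
#'
#' @param x Numerator (vectorised).
#' @param total Denominator.
#' @return Numeric vector of whole percentages.
#' @export
percent_of <- function(x, total) {
  if (any(total <= 0)) abort("`total` must be positive.")
  round_half_up(100 * x / total)
}

# Local civil time from UTC via a fixed site offset (no DST: analysis days
# are calendar days at a fixed offset).
local_time <- function(timestamp, utc_offset_hours) {
  timestamp + utc_offset_hours * 3600
}

local_date <- function(timestamp, utc_offset_hours) {
  as.Date(local_time(timestamp, utc_offset_hours), tz = "UTC")
}

knots_to_mps <- function(kn) kn * 1852 / 3600

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

# Absolute angular difference on the circle, in [0, 180].
angle_diff <- function(a, b) {
  d <- abs(a - b) %% 360
  ifelse(d > 180, 360 - d, d)
}

stars_for_p <- function(p) {
  dplyr::case_when(
    is.na(p) ~ "",
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ ""
  )
}
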