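#' Flag maintenance and outlier days for exclusion
#'
#' Reproduces the day-level quality filter: tracks beginning on a
#' maintenance day or the day immediately before or after are excluded;
#' then, among the remaining observed days, days whose log-transformed
#' (natural log) daily track count lies more than `sd_mult` standard
#' deviations from the site mean are excluded as likely weather-degraded.
#' Outlier statistics are computed after maintenance-day removal. Days are
#' the site's local calendar days (track start time shifted by the site
#' UTC offset).
#'
#' @param detections Detection tibble (tracks are attributed to the local
#'   date of their first point).
#' @param site A [site_geometry()] (for the UTC offset), or a numeric UTC
#'   offset in hours.
#' @param maintenance_days A `Date` vector (may be empty).
#' @param sd_mult Outlier threshold in standard deviations (default 2).
#' @return A `day_filter` object: tibbles of daily counts and the three
#'   disjoint day sets (`maintenance`, `outlier`, `analysis`), plus the
#'   log-count mean and sd.
#' @export
flag_excluded_days <- function(detections, site, maintenance_days = as.Date(character()),
                               sd_mult = 2) {
  offset <- if (is_site_geometry(site)) site$utc_offset_hours else site
  maintenance_days <- as.Date(maintenance_days)
  starts <- detections |>
    group_by(.data$track_id) |>
    summarise(start_time = min(.data$timestamp), .groups = "drop") |>
    mutate(start_day = local_date(.data$start_time, offset))
  daily <- count(starts, .data$start_day, name = "n_tracks")

  excluded_maintenance <- sort(unique(c(
    maintenance_days, maintenance_days - 1, maintenance_days + 1)))
  remaining <- daily[!(daily$start_day %in% excluded_maintenance), ]

  log_mean <- NA_real_; log_sd <- NA_real_
  outlier_days <- as.Date(character())
  if (nrow(remaining) < 3) {
    if (nrow(remaining) > 0) {
      warn("Fewer than 3 days remain after maintenance exclusion; log-count outlier step skipped.")
    }
  } else {
    ln <- log(remaining$n_tracks)
    log_mean <- mean(ln)
    log_sd <- stats::sd(ln)
    if (log_sd > 0) {
      outlier_days <- remaining$start_day[abs(ln - log_mean) > sd_mult * log_sd]
    }
  }
  analysis_days <- setdiff_dates(remaining$start_day, outlier_days)
  structure(
    list(
      site_id = if (is_site_geometry(site)) site$site_id else NA_character_,
      daily_counts = daily,
      excluded_maintenance_days = excluded_maintenance[
        excluded_maintenance %in% daily$start_day],
      excluded_outlier_days = outlier_days,
      analysis_days = analysis_days,
      log_mean = log_mean, log_sd = log_sd, sd_mult = sd_mult
    ),
    class = "day_filter"
  )
}

setdiff_dates <- function(a, b) sort(as.Date(setdiff(a, b), origin = "1970-01-01"))

#' @export
print.day_filter <- function(x, ...) {
  cat(sprintf(
    "<day_filter> %s: %d observed days; %d maintenance-excluded, %d outlier-excluded, %d analysis days\n",
    x$site_id %||% "?", nrow(x$daily_counts),
    length(x$excluded_maintenance_days), length(x$excluded_outlier_days),
    length(x$analysis_days)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.day_filter <- function(x, ...) {
  tibble(
    start_day = x$daily_counts$start_day,
    n_tracks = x$daily_counts$n_tracks,
    status = dplyr::case_when(
      x$daily_counts$start_day %in% x$excluded_maintenance_days ~ "maintenance",
      x$daily_counts$start_day %in% x$excluded_outlier_days ~ "outlier",
      TRUE ~ "analysis"
    )
  )
}

#' @exportS3Method generics::glance
glance.day_filter <- function(x, ...) {
  tibble(
    n_observed_days = nrow(x$daily_counts),
    n_maintenance_excluded = length(x$excluded_maintenance_days),
    n_outlier_excluded = length(x$excluded_outlier_days),
    n_analysis_days = length(x$analysis_days),
    log_mean = x$log_mean, log_sd = x$log_sd
  )
}

#' Percentage of the study period removed by the day filter
#'
#' @param n_analysis_days Number of retained analysis days.
#' @param n_total_days Number of days in the study period.
#' @return Whole percent of days removed (half-away-from-zero rounding).
#' @export
percent_days_removed <- function(n_analysis_days, n_total_days) {
  percent_of(n_total_days - n_analysis_days, n_total_days)
}

#' Restrict detections to analysis days
#'
#' Drops all points of tracks whose local start day is not an analysis day.
#'
#' @param detections Detection tibble.
#' @param day_filter A `day_filter` from [flag_excluded_days()].
#' @param site [site_geometry()] or numeric UTC offset.
#' @return Filtered tibble.
#' @export
filter_analysis_days <- function(detections, day_filter, site) {
  offset <- if (is_site_geometry(site)) site$utc_offset_hours else site
  starts <- detections |>
    group_by(.data$track_id) |>
    summarise(start_time = min(.data$timestamp), .groups = "drop") |>
    mutate(start_day = local_date(.data$start_time, offset))
  keep_ids <- starts$track_id[starts$start_day %in% day_filter$analysis_days]
  detections[detections$track_id %in% keep_ids, ]
}

#' Serialize a day-filter report to JSON
#'
#' @param x A `day_filter`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_day_filter_json <- function(x, path) {
  jsonlite::write_json(list(
    site_id = x$site_id,
    log_mean = x$log_mean, log_sd = x$log_sd, sd_mult = x$sd_mult,
    excluded_maintenance_days = as.character(x$excluded_maintenance_days),
    excluded_outlier_days = as.character(x$excluded_outlier_days),
    analysis_days = as.character(x$analysis_days),
    daily_counts = x$daily_counts |>
      mutate(start_day = as.character(.data$start_day))
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
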