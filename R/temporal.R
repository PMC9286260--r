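#' Fishing-season calendar
#'
#' A calendar of fisheries with seasonal closures: each fishery has an
#' identifier, the activity pattern it maps to (`focal`, `linear` or
#' `both`), the sites it applies to, and a set of non-overlapping inclusive
#' open-date intervals.
#'
#' @param fisheries A tibble (or data frame) with columns `fishery_id`,
#'   `pattern`, `sites` (list column of character vectors) and `open`
#'   (list column of data frames with `start`, `end` `Date`s).
#' @return A `season_calendar` object.
#' @export
season_calendar <- function(fisheries) {
  fisheries <- as_tibble(fisheries)
  stopifnot(all(c("fishery_id", "pattern", "sites", "open") %in% names(fisheries)))
  if (!all(fisheries$pattern %in% c("focal", "linear", "both"))) {
    abort("`pattern` must be one of focal, linear, both.")
  }
  fisheries$open <- lapply(fisheries$open, function(iv) {
    iv <- as_tibble(iv)
    iv$start <- as.Date(iv$start); iv$end <- as.Date(iv$end)
    iv <- iv[order(iv$start), ]
    if (any(iv$end < iv$start)) abort("Open interval with end before start.")
    if (nrow(iv) > 1 && any(iv$start[-1] <= iv$end[-nrow(iv)])) {
      abort("Open intervals overlap.")
    }
    iv
  })
  structure(list(fisheries = fisheries), class = "season_calendar")
}

#' @export
print.season_calendar <- function(x, ...) {
  cat(sprintf("<season_calendar> %d fisheries\n", nrow(x$fisheries)))
  for (i in seq_len(nrow(x$fisheries))) {
    f <- x$fisheries[i, ]
    cat(sprintf("  %s (%s; sites: %s): %d open interval(s)\n",
                f$fishery_id, f$pattern,
                paste(f$sites[[1]], collapse = ","), nrow(f$open[[1]])))
  }
  invisible(x)
}

#' Read / write a season calendar as YAML
#'
#' Schema: a top-level `fisheries` list; each entry has `fishery_id`,
#' `pattern`, `sites` (list of site ids) and `open` (list of
#' `{start, end}` ISO dates).
#'
#' @param path YAML file path.
#' @return A `season_calendar` / `path` invisibly.
#' @export
read_season_calendar <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$fisheries)) abort("Calendar YAML has no `fisheries` key.")
  rows <- lapply(y$fisheries, function(f) {
    tibble(
      fishery_id = f$fishery_id,
      pattern = f$pattern %||% "both",
      sites = list(unlist(f$sites) %||% character()),
      open = list(tibble(
        start = as.Date(vapply(f$open, function(iv) iv$start, character(1))),
        end = as.Date(vapply(f$open, function(iv) iv$end, character(1)))
      ))
    )
  })
  season_calendar(bind_rows(rows))
}

#' @rdname read_season_calendar
#' @param calendar A `season_calendar`.
#' @export
write_season_calendar <- function(calendar, path) {
  fisheries <- lapply(seq_len(nrow(calendar$fisheries)), function(i) {
    f <- calendar$fisheries[i, ]
    list(
      fishery_id = f$fishery_id,
      pattern = f$pattern,
      sites = as.list(f$sites[[1]]),
      open = lapply(seq_len(nrow(f$open[[1]])), function(j) {
        list(start = as.character(f$open[[1]]$start[j]),
             end = as.character(f$open[[1]]$end[j]))
      })
    )
  })
  yaml::write_yaml(list(fisheries = fisheries), path)
  invisible(path)
}

#' Open/closed season state for dates
#'
#' @param dates `Date` vector.
#' @param calendar A [season_calendar()].
#' @param fishery_id Fishery to evaluate.
#' @return Character vector `"open"`/`"closed"`.
#' @export
season_state <- function(dates, calendar, fishery_id) {
  stopifnot(inherits(calendar, "season_calendar"))
  i <- match(fishery_id, calendar$fisheries$fishery_id)
  if (is.na(i)) abort(sprintf("Unknown fishery '%s'.", fishery_id))
  iv <- calendar$fisheries$open[[i]]
  dates <- as.Date(dates)
  open <- rep(FALSE, length(dates))
  for (j in seq_len(nrow(iv))) {
    open <- open | (dates >= iv$start[j] & dates <= iv$end[j])
  }
  ifelse(open, "open", "closed")
}

#' Track-level temporal attributes
#'
#' Tags every track with attributes of its first detection point: local day
#' of week, hour of day (0–23) and weekend flag (Saturday/Sunday).
#'
#' @param detections Detection tibble.
#' @param site A [site_geometry()] or numeric UTC offset.
#' @return Tibble: `track_id`, `start_time`, `start_day`, `day_of_week`,
#'   `hour_of_day`, `is_weekend`.
#' @export
tag_tracks <- function(detections, site) {
  offset <- if (is_site_geometry(site)) site$utc_offset_hours else site
  detections |>
    group_by(.data$track_id) |>
    summarise(start_time = min(.data$timestamp), .groups = "drop") |>
    mutate(
      local = local_time(.data$start_time, offset),
      start_day = as.Date(.data$local, tz = "UTC"),
      day_of_week = lubridate::wday(.data$local, label = TRUE, abbr = FALSE,
                                    week_start = 1, locale = "C"),
      hour_of_day = lubridate::hour(.data$local),
      is_weekend = .data$day_of_week %in% c("Saturday", "Sunday")
    ) |>
    select(-"local")
}

#' Point-level day/night tags
#'
#' Flags every detection point day or night from site-specific sunrise and
#' sunset on the point's local date. Every point is exactly one of the two.
#'
#' @param detections Detection tibble.
#' @param site A [site_geometry()] (radar location supplies the
#'   latitude/longitude for the solar calculation).
#' @return The input with `is_day` appended.
#' @export
tag_day_night <- function(detections, site) {
  stopifnot(is_site_geometry(site))
  loc <- local_time(detections$timestamp, site$utc_offset_hours)
  d <- as.Date(loc, tz = "UTC")
  ud <- unique(d)
  st <- sun_times(ud, site$radar_lat, site$radar_lon, site$utc_offset_hours)
  i <- match(d, st$date)
  mutate(detections,
         is_day = loc >= st$sunrise[i] & loc < st$sunset[i])
}
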