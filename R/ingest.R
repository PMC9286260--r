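#' Read a radar detection stream from CSV
#'
#' Expects columns `track_id, timestamp, lon, lat, sog_kn, heading_deg` with
#' ISO-8601 UTC timestamps. Rows that fail to parse or have any missing
#' attribute are collected into a reject report (attached as the
#' `"rejects"` attribute with the originating line numbers), not silently
#' dropped.
#'
#' @param path CSV file path.
#' @return A tibble of detections; `detection_rejects()` retrieves the
#'   reject report.
#' @export
read_detections <- function(path) {
  required <- c("track_id", "timestamp", "lon", "lat", "sog_kn", "heading_deg")
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(sprintf("Detection CSV is missing column(s): %s.",
                  paste(missing_cols, collapse = ", ")))
  }
  raw <- mutate(raw, .line = row_number() + 1L)  # +1 for the header line
  parsed <- mutate(
    raw,
    timestamp_p = lubridate::ymd_hms(.data$timestamp, tz = "UTC", quiet = TRUE),
    lon_p = suppressWarnings(as.numeric(.data$lon)),
    lat_p = suppressWarnings(as.numeric(.data$lat)),
    sog_p = suppressWarnings(as.numeric(.data$sog_kn)),
    hdg_p = suppressWarnings(as.numeric(.data$heading_deg))
  )
  bad <- with(parsed,
    is.na(track_id) | track_id == "" |
    is.na(timestamp_p) | is.na(lon_p) | is.na(lat_p) |
    is.na(sog_p) | is.na(hdg_p) | sog_p < 0)
  rejects <- parsed[bad, c(".line", required)]
  names(rejects)[1] <- "line"
  out <- parsed[!bad, ]
  out <- tibble(
    track_id = out$track_id,
    timestamp = out$timestamp_p,
    lon = out$lon_p, lat = out$lat_p,
    sog_kn = out$sog_p,
    heading_deg = out$hdg_p %% 360
  )
  if (nrow(rejects) > 0) {
    inform(sprintf("read_detections: %d row(s) rejected (see detection_rejects()).",
                   nrow(rejects)))
  }
  attr(out, "rejects") <- as_tibble(rejects)
  out
}

#' @rdname read_detections
#' @param detections A tibble returned by `read_detections()`.
#' @export
detection_rejects <- function(detections) {
  attr(detections, "rejects") %||%
    tibble(line = integer(), track_id = character(), timestamp = character(),
           lon = character(), lat = character(), sog_kn = character(),
           heading_deg = character())
}

#' Write detections in the ingest CSV dialect
#'
#' @param detections Detection tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_detections <- function(detections, path) {
  out <- tibble(
    track_id = detections$track_id,
    timestamp = format(detections$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    lon = detections$lon, lat = detections$lat,
    sog_kn = detections$sog_kn, heading_deg = detections$heading_deg
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Deduplicate and validate detection points
#'
#' Within each track, exact duplicates (identical timestamp and coordinates)
#' collapse to a single point; points with any missing attribute are
#' dropped; points are stably ordered by time within track. Idempotent.
#'
#' @param detections Detection tibble.
#' @return Deduplicated tibble; attribute `"n_removed"` records the number
#'   of rows removed.
#' @export
dedupe_detections <- function(detections) {
  detections <- as_tibble(detections)
  n0 <- nrow(detections)
  complete <- stats::complete.cases(
    detections[, c("track_id", "timestamp", "lon", "lat", "sog_kn", "heading_deg")])
  out <- detections[complete, ]
  out <- out[order(out$track_id, out$timestamp, method = "radix"), ]
  dup <- duplicated(out[, c("track_id", "timestamp", "lon", "lat")])
  out <- out[!dup, ]
  attr(out, "n_removed") <- n0 - nrow(out)
  out
}

#' Clip detections to the site's full detection range
#'
#' Retains only points inside the full-range polygon (detection-range disc
#' minus exclusion masks). Tracks may become fragmented; the original
#' `track_id` is retained.
#'
#' @param detections Detection tibble with planar `x`, `y`.
#' @param regions A `region_set` from [build_regions()].
#' @return Filtered tibble; attribute `"n_removed"` records drops.
#' @export
clip_to_range <- function(detections, regions) {
  stopifnot(inherits(regions, "region_set"))
  detections <- as_tibble(detections)
  keep <- points_in_poly(detections$x, detections$y, regions$polys$full_range)
  out <- detections[keep, ]
  attr(out, "n_removed") <- sum(!keep)
  out
}
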