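#' Run configuration
#'
#' Collects paths and thresholds for an end-to-end pipeline run. Thresholds
#' default to the standard analysis settings; paths are resolved at run
#' time.
#'
#' @param site_path Site GeoJSON path.
#' @param detections_path Detection CSV path.
#' @param out_dir Output directory.
#' @param calendar_path Optional season-calendar YAML.
#' @param maintenance_days `Date` vector (or path handled by the caller).
#' @param k,speed_band,turn_thresh,speed_dev_thresh,min_run Behaviour
#'   classification settings.
#' @param sd_mult Day-filter outlier threshold (standard deviations).
#' @param vicinity_buffer_m,boundary_halfwidth_m,cell_size_m Geometry
#'   settings, metres.
#' @param seed RNG seed (only used by simulation subcommands).
#' @return A `run_config` list.
#' @export
run_config <- function(site_path, detections_path, out_dir,
                       calendar_path = NULL,
                       maintenance_days = as.Date(character()),
                       k = 12, speed_band = c(2, 6), turn_thresh = 15,
                       speed_dev_thresh = 0.25, min_run = 12, sd_mult = 2,
                       vicinity_buffer_m = 1000, boundary_halfwidth_m = 100,
                       cell_size_m = 246, seed = 1) {
  thr <- c(k, speed_band, turn_thresh, speed_dev_thresh, min_run, sd_mult,
           vicinity_buffer_m, boundary_halfwidth_m, cell_size_m)
  if (any(thr <= 0)) abort("All thresholds must be positive.")
  structure(
    list(site_path = site_path, detections_path = detections_path,
         out_dir = out_dir, calendar_path = calendar_path,
         maintenance_days = as.Date(maintenance_days),
         k = k, speed_band = speed_band, turn_thresh = turn_thresh,
         speed_dev_thresh = speed_dev_thresh, min_run = min_run,
         sd_mult = sd_mult, vicinity_buffer_m = vicinity_buffer_m,
         boundary_halfwidth_m = boundary_halfwidth_m,
         cell_size_m = cell_size_m, seed = seed),
    class = "run_config"
  )
}

#' Read a run configuration from YAML
#'
#' Top-level keys mirror the [run_config()] arguments; `maintenance_days`
#' is a list of ISO dates.
#'
#' @param path YAML path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list(
    site_path = y$site_path, detections_path = y$detections_path,
    out_dir = y$out_dir %||% ".",
    calendar_path = y$calendar_path,
    maintenance_days = as.Date(unlist(y$maintenance_days) %||% character())
  )
  for (nm in c("k", "turn_thresh", "speed_dev_thresh", "min_run", "sd_mult",
               "vicinity_buffer_m", "boundary_halfwidth_m", "cell_size_m",
               "seed")) {
    if (!is.null(y[[nm]])) args[[nm]] <- y[[nm]]
  }
  if (!is.null(y$speed_band)) args$speed_band <- unlist(y$speed_band)
  do.call(run_config, args)
}

#' Run the full monitoring pipeline
#'
#' Executes ingest, quality control, behaviour classification, activity
#' metrics and (when a calendar is configured) season comparisons, writing
#' a report bundle: reject report, day-filter JSON, per-point labels,
#' segments, daily records, summary tables, grid CSV/GeoJSON, region
#' GeoJSON, season-test CSV, and a run log recording every filter's
#' (before, after) counts. Any stage failure aborts with the stage name.
#'
#' @param config A [run_config()] (or a YAML path).
#' @return Invisibly, a list with all intermediate and final tables plus
#'   the `log` tibble of filter counts.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_rows <- list()
  note <- function(stage, before, after) {
    log_rows[[length(log_rows) + 1]] <<- tibble(
      stage = stage, n_before = before, n_after = after)
    inform(sprintf("[%s] %d -> %d", stage, before, after))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }

  site <- stage("read_site", read_site_geojson(config$site_path))
  det <- stage("read_detections", read_detections(config$detections_path))
  rejects <- detection_rejects(det)
  readr::write_csv(rejects, file.path(out_dir, "rejects.csv"), progress = FALSE)
  note("read_detections", nrow(det) + nrow(rejects), nrow(det))

  n0 <- nrow(det)
  det <- stage("dedupe", dedupe_detections(det))
  note("dedupe_and_validate", n0, nrow(det))

  regions <- stage("build_regions", build_regions(
    site, vicinity_buffer_m = config$vicinity_buffer_m,
    boundary_halfwidth_m = config$boundary_halfwidth_m))
  write_regions_geojson(regions, site, file.path(out_dir, "regions.geojson"))

  det <- stage("project", project_to_planar(det, site))
  n0 <- nrow(det)
  det <- stage("clip_to_range", clip_to_range(det, regions))
  note("clip_to_range", n0, nrow(det))

  dayf <- stage("flag_excluded_days", flag_excluded_days(
    det, site, maintenance_days = config$maintenance_days,
    sd_mult = config$sd_mult))
  write_day_filter_json(dayf, file.path(out_dir, "day_filter.json"))
  n0 <- nrow(det)
  det <- stage("filter_analysis_days", filter_analysis_days(det, dayf, site))
  note("filter_analysis_days", n0, nrow(det))

  screen <- stage("screen_false_targets", screen_false_targets(det))
  readr::write_csv(screen, file.path(out_dir, "target_screen.csv"),
                   progress = FALSE)
  n0 <- length(unique(det$track_id))
  det <- stage("remove_false_targets", remove_false_targets(det, screen))
  note("screen_false_targets (tracks)", n0, length(unique(det$track_id)))

  det <- stage("classify_behavior", classify_behavior(
    det, k = config$k, speed_band = config$speed_band,
    turn_thresh = config$turn_thresh,
    speed_dev_thresh = config$speed_dev_thresh, min_run = config$min_run))
  segs <- activity_segments(det)
  readr::write_csv(
    det |> select("track_id", "point_index", "timestamp", "lon", "lat",
                  "sog_kn", "heading_deg", "behavior_raw", "behavior",
                  "segment_id"),
    file.path(out_dir, "point_labels.csv"), progress = FALSE)
  readr::write_csv(segs, file.path(out_dir, "segments.csv"), progress = FALSE)

  records <- stage("daily_rollup", daily_rollup(det, regions, site)) |>
    normalize_by_area(regions)
  readr::write_csv(records, file.path(out_dir, "daily_records.csv"),
                   progress = FALSE)
  summary <- stage("summary_tables", summary_tables(
    records, analysis_days = stats::setNames(list(dayf$analysis_days),
                                             site$site_id)))
  readr::write_csv(summary, file.path(out_dir, "summary.csv"), progress = FALSE)

  grid <- stage("build_grid", build_grid(regions, config$cell_size_m))
  grid_hours <- stage("grid_rollup", grid_rollup(det, grid, normalize = TRUE))
  readr::write_csv(grid_hours, file.path(out_dir, "grid_hours.csv"),
                   progress = FALSE)
  write_grid_geojson(grid, site, file.path(out_dir, "grid.geojson"),
                     values = grid_hours |>
                       filter(.data$category == "all") |>
                       select("cell_id", "track_hours"))

  season_tests <- NULL
  if (!is.null(config$calendar_path)) {
    calendar <- stage("read_calendar", read_season_calendar(config$calendar_path))
    season_tests <- stage("season_comparison",
                          season_comparison(records, calendar))
    readr::write_csv(season_tests, file.path(out_dir, "season_tests.csv"),
                     progress = FALSE)
  }

  log <- bind_rows(log_rows)
  readr::write_csv(log, file.path(out_dir, "run_log.csv"), progress = FALSE)
  invisible(list(
    site = site, regions = regions, detections = det, rejects = rejects,
    day_filter = dayf, screen = screen, segments = segs, records = records,
    summary = summary, grid = grid, grid_hours = grid_hours,
    season_tests = season_tests, log = log
  ))
}
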