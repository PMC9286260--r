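# Activity metrics: track counts, cumulative track hours, area-normalised
# daily activity, and the gridded effort surface.

# Hours over maximal runs of TRUE in `flag`, where a run's duration is the
# time between its first and last point (single-point runs contribute 0).
run_hours <- function(times, flag) {
  if (length(times) == 0 || !any(flag)) return(0)
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  ok <- r$values
  sum(as.numeric(difftime(times[ends[ok]], times[starts[ok]], units = "hours")))
}

#' Track hours within a spatial unit
#'
#' For each track, identifies maximal runs of consecutive points inside the
#' unit polygon (optionally restricted to points carrying a given activity
#' label) and sums the first-to-last time difference of each run. A track
#' that exits and re-enters the unit accrues no outside time; single-point
#' runs count as presence but contribute zero hours.
#'
#' @param detections Detection tibble with planar `x`, `y`, time-ordered
#'   within track (a `behavior` column is required when `label` is given).
#' @param unit A planar polygon (list of rings) or a `region_set` region
#'   polygon.
#' @param label Optional activity label (`"focal"`, `"linear"`) restricting
#'   the qualifying points; `"potential_fishing"` means focal or linear.
#' @return Tibble `track_id`, `hours`.
#' @export
track_hours_in_unit <- function(detections, unit, label = NULL) {
  inside <- points_in_poly(detections$x, detections$y, unit)
  flag <- inside & .category_flag(detections, label %||% "all")
  detections |>
    mutate(.flag = flag) |>
    group_by(.data$track_id) |>
    arrange(.data$timestamp, .by_group = TRUE) |>
    summarise(hours = run_hours(.data$timestamp, .data$.flag),
              .groups = "drop")
}

.category_flag <- function(det, category) {
  if (category == "all") return(rep(TRUE, nrow(det)))
  b <- as.character(det$behavior)
  switch(category,
    focal = b == "focal",
    linear = b == "linear",
    potential_fishing = b %in% c("focal", "linear"),
    non_fishing = b == "other",
    abort(sprintf("Unknown category '%s'.", category))
  )
}

.region_flag <- function(region_lab, reporting_region) {
  r <- as.character(region_lab)
  switch(reporting_region,
    full_range = r != "outside",
    outside_vicinity = r == "range_only",
    vicinity = r %in% c("inner", "boundary", "outer"),
    inner = r == "inner",
    boundary = r == "boundary",
    outer = r == "outer",
    abort(sprintf("Unknown reporting region '%s'.", reporting_region))
  )
}

REPORTING_REGIONS <- c("full_range", "outside_vicinity", "vicinity",
                       "inner", "boundary", "outer")
ACTIVITY_CATEGORIES <- c("all", "non_fishing", "potential_fishing",
                         "focal", "linear")

#' Daily activity records per region and category
#'
#' Rolls classified detections up to one record per (local start date,
#' reporting region, activity category): the number of distinct tracks with
#' at least one qualifying point in the region, and the cumulative track
#' hours there (summed across tracks regardless of temporal overlap, so
#' hours can exceed 24 per day). Tracks are attributed to the local
#' calendar day of their first detection. A track with both focal and
#' linear segments counts once in each of `focal`, `linear`, and once in
#' `potential_fishing`; `non_fishing` counts tracks with no activity of
#' interest in the region, so `non_fishing + potential_fishing = all` for
#' counts.
#'
#' @param detections Output of [classify_behavior()] with planar `x`, `y`.
#' @param regions A `region_set`.
#' @param site [site_geometry()] or numeric UTC offset (for local dates).
#' @param stratum Optional point-level logical column name (e.g. `is_day`)
#'   restricting the rollup; used for day/night strata.
#' @return Tibble: `date`, `site_id`, `region`, `category`, `track_count`,
#'   `track_hours`.
#' @export
daily_rollup <- function(detections, regions, site, stratum = NULL) {
  offset <- if (is_site_geometry(site)) site$utc_offset_hours else site
  site_id <- if (is_site_geometry(site)) site$site_id else regions$site_id
  empty <- tibble(date = as.Date(character()), site_id = character(),
                  region = character(), category = character(),
                  track_count = integer(), track_hours = numeric())
  if (nrow(detections) == 0) return(empty)
  det <- assign_region(detections, regions) |>
    group_by(.data$track_id) |>
    arrange(.data$timestamp, .by_group = TRUE) |>
    mutate(start_day = local_date(min(.data$timestamp), offset)) |>
    ungroup()
  strat_flag <- if (is.null(stratum)) rep(TRUE, nrow(det)) else det[[stratum]]

  out <- list()
  for (rr in REPORTING_REGIONS) {
    rflag <- .region_flag(det$region, rr)
    flags <- list()
    for (cat in ACTIVITY_CATEGORIES) {
      flags[[cat]] <- rflag & strat_flag & .category_flag(det, cat)
    }
    for (cat in ACTIVITY_CATEGORIES) {
      f <- flags[[cat]]
      if (cat == "non_fishing") {
        # tracks present in the region without any activity of interest there
        present <- det |>
          mutate(.f = flags[["all"]], .pf = flags[["potential_fishing"]]) |>
          group_by(.data$start_day, .data$track_id) |>
          summarise(any_all = any(.data$.f), any_pf = any(.data$.pf),
                    .groups = "drop")
        counts <- present |>
          filter(.data$any_all & !.data$any_pf) |>
          count(.data$start_day, name = "track_count")
      } else {
        counts <- det |>
          filter(f) |>
          distinct(.data$start_day, .data$track_id) |>
          count(.data$start_day, name = "track_count")
      }
      hours <- det |>
        mutate(.f = f) |>
        group_by(.data$start_day, .data$track_id) |>
        summarise(h = run_hours(.data$timestamp, .data$.f), .groups = "drop") |>
        group_by(.data$start_day) |>
        summarise(track_hours = sum(.data$h), .groups = "drop")
      rec <- dplyr::full_join(counts, hours, by = "start_day") |>
        mutate(track_count = dplyr::coalesce(.data$track_count, 0L),
               track_hours = dplyr::coalesce(.data$track_hours, 0)) |>
        filter(.data$track_count > 0 | .data$track_hours > 0)
      if (nrow(rec) > 0) {
        out[[length(out) + 1]] <- mutate(rec, region = rr, category = cat)
      }
    }
  }
  if (length(out) == 0) return(empty)
  bind_rows(out) |>
    mutate(site_id = site_id) |>
    select(date = "start_day", "site_id", "region", "category",
           "track_count", "track_hours") |>
    arrange(.data$date, match(.data$region, REPORTING_REGIONS),
            match(.data$category, ACTIVITY_CATEGORIES))
}

#' Normalise daily activity records by region area
#'
#' Adds `hours_per_km2 = track_hours / area_km2` using the region areas of
#' a `region_set` (or an explicit areas tibble).
#'
#' @param records Output of [daily_rollup()].
#' @param regions A `region_set`, or a tibble with `region`, `area_km2`.
#' @return `records` with `area_km2` and `hours_per_km2` columns.
#' @export
normalize_by_area <- function(records, regions) {
  areas <- if (inherits(regions, "region_set")) regions$areas else as_tibble(regions)
  if (any(areas$area_km2 <= 0)) {
    bad <- areas$region[areas$area_km2 <= 0]
    abort(sprintf("Non-positive area for region(s): %s.",
                  paste(bad, collapse = ", ")))
  }
  records |>
    left_join(areas, by = "region") |>
    mutate(hours_per_km2 = .data$track_hours / .data$area_km2)
}

#' Gridded track hours
#'
#' Accumulates track hours per grid cell (runs of consecutive points within
#' one cell, per track), optionally by activity category, with an optional
#' min-max normalisation of cell values to [0, 1] for rendering.
#'
#' @param detections Output of [classify_behavior()] with planar `x`, `y`.
#' @param grid An `activity_grid` from [build_grid()].
#' @param categories Activity categories to accumulate.
#' @param normalize Add a `relative` column (min-max per category).
#' @return Tibble: `cell_id`, `category`, `track_hours` (and `relative`).
#' @export
grid_rollup <- function(detections, grid,
                        categories = c("all", "focal", "linear"),
                        normalize = FALSE) {
  det <- as_tibble(detections)
  det$cell_id <- grid_cell_of(det$x, det$y, grid)
  out <- list()
  for (cat in categories) {
    cf <- .category_flag(det, cat)
    acc <- det |>
      mutate(.cf = cf) |>
      group_by(.data$track_id) |>
      arrange(.data$timestamp, .by_group = TRUE) |>
      dplyr::group_modify(function(d, key) {
        keyv <- ifelse(d$.cf & !is.na(d$cell_id), d$cell_id, NA_integer_)
        r <- rle(paste(keyv))
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1
        ok <- r$values != "NA"
        tibble(
          cell_id = as.integer(r$values[ok]),
          hours = as.numeric(difftime(d$timestamp[ends[ok]],
                                      d$timestamp[starts[ok]],
                                      units = "hours"))
        )
      }) |>
      ungroup() |>
      group_by(.data$cell_id) |>
      summarise(track_hours = sum(.data$hours), .groups = "drop") |>
      mutate(category = cat)
    out[[cat]] <- acc
  }
  res <- bind_rows(out) |>
    select("cell_id", "category", "track_hours")
  if (normalize) {
    res <- res |>
      group_by(.data$category) |>
      mutate(relative = if (dplyr::n() > 1 &&
                            max(.data$track_hours) > min(.data$track_hours)) {
        (.data$track_hours - min(.data$track_hours)) /
          (max(.data$track_hours) - min(.data$track_hours))
      } else {
        ifelse(.data$track_hours > 0, 1, 0)
      }) |>
      ungroup()
  }
  res
}

#' Site and overall summary tables
#'
#' Aggregates daily activity records into the reporting summaries: per site
#' and overall, for each region and category, the total (`Sum`) and the
#' daily mean and standard deviation over analysis days (days without a
#' record count as zero), plus whole-number percentages of each site's
#' all-observed full-range total (half-away-from-zero rounding).
#'
#' @param records Output of [daily_rollup()] (optionally after
#'   [normalize_by_area()]), possibly for several sites.
#' @param analysis_days Optional named list mapping `site_id` to the `Date`
#'   vector of analysis days (defaults to the dates observed per site).
#' @return Tibble with `site_id` (including `"overall"`), `region`,
#'   `category`, `n_days`, `count_sum`, `count_daily_mean`,
#'   `count_daily_sd`, `hours_sum`, `hours_daily_mean`, `hours_daily_sd`,
#'   `count_pct`, `hours_pct`.
#' @export
summary_tables <- function(records, analysis_days = NULL) {
  records <- as_tibble(records)
  if (nrow(records) == 0) {
    abort("No daily activity records to summarise (all days excluded?).")
  }
  sites <- unique(records$site_id)
  per_site <- lapply(sites, function(s) {
    rec <- records[records$site_id == s, ]
    days <- if (!is.null(analysis_days) && !is.null(analysis_days[[s]])) {
      as.Date(analysis_days[[s]])
    } else {
      sort(unique(rec$date))
    }
    nd <- length(days)
    grid <- tidyr::expand_grid(
      date = days,
      region = unique(rec$region),
      category = unique(rec$category)
    )
    full <- grid |>
      left_join(rec, by = c("date", "region", "category")) |>
      mutate(track_count = dplyr::coalesce(.data$track_count, 0L),
             track_hours = dplyr::coalesce(.data$track_hours, 0))
    full |>
      group_by(.data$region, .data$category) |>
      summarise(
        n_days = nd,
        count_sum = sum(.data$track_count),
        count_daily_mean = mean(.data$track_count),
        count_daily_sd = if (nd > 1) stats::sd(.data$track_count) else 0,
        hours_sum = sum(.data$track_hours),
        hours_daily_mean = mean(.data$track_hours),
        hours_daily_sd = if (nd > 1) stats::sd(.data$track_hours) else 0,
        .groups = "drop"
      ) |>
      mutate(site_id = s)
  })
  site_tbl <- bind_rows(per_site)
  overall <- site_tbl |>
    group_by(.data$region, .data$category) |>
    summarise(
      n_days = sum(.data$n_days),
      count_sum = sum(.data$count_sum),
      count_daily_mean = NA_real_, count_daily_sd = NA_real_,
      hours_sum = sum(.data$hours_sum),
      hours_daily_mean = NA_real_, hours_daily_sd = NA_real_,
      .groups = "drop"
    ) |>
    mutate(site_id = "overall")
  res <- bind_rows(site_tbl, overall)
  denom <- res |>
    filter(.data$region == "full_range", .data$category == "all") |>
    select("site_id", denom_count = "count_sum", denom_hours = "hours_sum")
  res |>
    left_join(denom, by = "site_id") |>
    mutate(
      count_pct = ifelse(.data$denom_count > 0,
                         percent_of(.data$count_sum, .data$denom_count), NA_real_),
      hours_pct = ifelse(.data$denom_hours > 0,
                         percent_of(.data$hours_sum, .data$denom_hours), NA_real_)
    ) |>
    select(-"denom_count", -"denom_hours") |>
    select("site_id", "region", "category", dplyr::everything()) |>
    arrange(match(.data$site_id, c(setdiff(unique(.data$site_id), "overall"), "overall")),
            match(.data$region, REPORTING_REGIONS),
            match(.data$category, ACTIVITY_CATEGORIES))
}
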