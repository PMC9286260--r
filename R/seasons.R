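#' Closed/open season comparisons of daily activity
#'
#' For every fishery in the calendar, MPA region and temporal stratum,
#' compares positive daily activity (hours per km²) between the closed and
#' open season with the exact two-sample quantile test (q = 0.5),
#' one-sided for greater activity in the open season. Days with zero
#' activity are ignored. A combination whose closed or open side is empty
#' is reported as skipped rather than tested.
#'
#' @param records Daily activity records (from [daily_rollup()] +
#'   [normalize_by_area()]): columns `date`, `site_id`, `region`,
#'   `category`, `hours_per_km2`, and `stratum` (`"day"`/`"night"`) for
#'   day/night strata (build those with `daily_rollup(stratum = "is_day")`
#'   etc. and label them yourself).
#' @param calendar A [season_calendar()].
#' @param regions_tested Regions to compare (default inner, boundary,
#'   outer).
#' @param strata Subset of `c("all", "day", "night", "weekday",
#'   "weekend")`.
#' @param alpha_stars Significance levels for the star annotation.
#' @return Tibble: `fishery_id`, `site_id`, `region`, `stratum`, `m`, `n`,
#'   `median_closed`, `median_open`, `p_value`, `stars`, `skipped`.
#' @export
season_comparison <- function(records, calendar,
                              regions_tested = c("inner", "boundary", "outer"),
                              strata = c("all", "weekday", "weekend"),
                              alpha_stars = c(0.05, 0.01, 0.001)) {
  stopifnot(inherits(calendar, "season_calendar"))
  records <- as_tibble(records)
  has_stratum <- "stratum" %in% names(records)
  if (any(strata %in% c("day", "night")) && !has_stratum) {
    abort("Day/night strata need records with a `stratum` column.")
  }
  out <- list()
  for (i in seq_len(nrow(calendar$fisheries))) {
    f <- calendar$fisheries[i, ]
    category <- switch(f$pattern, focal = "focal", linear = "linear",
                       both = "potential_fishing")
    f_sites <- f$sites[[1]]
    sites <- intersect(unique(records$site_id),
                       if (length(f_sites)) f_sites else unique(records$site_id))
    for (s in sites) {
      for (rg in regions_tested) {
        for (st in strata) {
          rec <- records[records$site_id == s & records$region == rg &
                           records$category == category, ]
          if (st %in% c("day", "night")) {
            rec <- rec[has_stratum & rec$stratum == st, ]
          } else if (has_stratum) {
            rec <- rec[rec$stratum == "all", ]
          }
          if (st == "weekday") {
            rec <- rec[!(lubridate::wday(rec$date, week_start = 1) %in% 6:7), ]
          } else if (st == "weekend") {
            rec <- rec[lubridate::wday(rec$date, week_start = 1) %in% 6:7, ]
          }
          rec <- rec[rec$hours_per_km2 > 0, ]
          state <- season_state(rec$date, calendar, f$fishery_id)
          closed <- rec$hours_per_km2[state == "closed"]
          open <- rec$hours_per_km2[state == "open"]
          if (length(closed) == 0 || length(open) == 0) {
            out[[length(out) + 1]] <- tibble(
              fishery_id = f$fishery_id, site_id = s, region = rg,
              stratum = st, m = length(closed), n = length(open),
              median_closed = NA_real_, median_open = NA_real_,
              p_value = NA_real_, stars = "", skipped = TRUE)
            next
          }
          qt <- quantile_test(closed, open, q = 0.5, alternative = "greater")
          out[[length(out) + 1]] <- tibble(
            fishery_id = f$fishery_id, site_id = s, region = rg,
            stratum = st, m = qt$m, n = qt$n,
            median_closed = qt$median_x, median_open = qt$median_y,
            p_value = qt$p_value, stars = stars_for_p(qt$p_value),
            skipped = FALSE)
        }
      }
    }
  }
  if (length(out) == 0) {
    return(tibble(fishery_id = character(), site_id = character(),
                  region = character(), stratum = character(),
                  m = integer(), n = integer(),
                  median_closed = numeric(), median_open = numeric(),
                  p_value = numeric(), stars = character(),
                  skipped = logical()))
  }
  bind_rows(out)
}
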