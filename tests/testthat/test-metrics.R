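t0 <- as.POSIXct("2019-06-01 18:00:00", tz = "UTC")
unit_sq <- mpatrack:::rect_poly(-500, 2500, 500, 3500)  # inside the MPA

test_that("track hours sum first-to-last time per maximal in-unit run", {
  # fully inside for one hour
  det <- tibble(track_id = "T1", timestamp = t0 + seq(0, 3600, by = 60),
                x = 0, y = 3000)
  expect_equal(track_hours_in_unit(det, unit_sq)$hours, 1)

  # two in-unit runs: 0-600 s and 1200-1800 s -> 1200 s total
  tt <- c(seq(0, 600, 60), seq(660, 1140, 60), seq(1200, 1800, 60))
  inside <- c(rep(TRUE, 11), rep(FALSE, 9), rep(TRUE, 11))
  det2 <- tibble(track_id = "T2", timestamp = t0 + tt,
                 x = ifelse(inside, 0, 5000), y = 3000)
  expect_equal(track_hours_in_unit(det2, unit_sq)$hours, 1200 / 3600)

  # a single in-unit point is presence with zero duration
  det3 <- tibble(track_id = "T3", timestamp = t0 + c(0, 60, 120),
                 x = c(5000, 0, 5000), y = 3000)
  expect_equal(track_hours_in_unit(det3, unit_sq)$hours, 0)
})

test_that("track hours can be restricted to labelled activity points", {
  det <- tibble(track_id = "T1", timestamp = t0 + seq(0, 120, 2),
                x = 0, y = 3000,
                behavior = factor(c(rep("other", 20), rep("focal", 41)),
                                  levels = c("focal", "linear", "other")))
  expect_equal(track_hours_in_unit(det, unit_sq, label = "focal")$hours,
               80 / 3600)
  expect_equal(track_hours_in_unit(det, unit_sq,
                                   label = "potential_fishing")$hours,
               80 / 3600)
})

make_classified <- function(...) {
  det <- dplyr::bind_rows(...)
  classify_behavior(det)
}

test_that("daily rollup counts concurrent hours cumulatively", {
  regions <- square_regions()
  # three concurrent 1-h tracks loitering inside the MPA centre
  tracks <- lapply(1:3, function(i) {
    tibble(track_id = paste0("C", i),
           timestamp = t0 + seq(0, 3600, by = 2),
           x = -1000 + i * 10, y = 4000, sog_kn = 1, heading_deg = 0,
           lon = 0, lat = 0)
  })
  det <- make_classified(!!!tracks)
  rec <- daily_rollup(det, regions, square_site())
  inner_all <- rec[rec$region == "inner" & rec$category == "all", ]
  expect_equal(inner_all$track_count, 3)
  expect_equal(inner_all$track_hours, 3)
  # slow loitering is focal: the full hour counts as potential fishing
  inner_pf <- rec[rec$region == "inner" & rec$category == "potential_fishing", ]
  expect_equal(inner_pf$track_count, 3)
  expect_equal(inner_pf$track_hours, 3)
})

test_that("a track with both patterns counts once in each category", {
  regions <- square_regions()
  v <- 3 * 1852 / 3600
  n1 <- 40
  # steady tow then loiter, all inside the MPA interior
  tow <- tibble(point = 1:n1, x = -2000 + (1:n1) * v * 2, y = 4000,
                sog_kn = 3, heading_deg = 90)
  loiter <- tibble(point = 1:30, x = -2000 + n1 * v * 2 + (1:30),
                   y = 4000, sog_kn = 1, heading_deg = 90)
  det <- tibble(
    track_id = "MX",
    timestamp = t0 + 2 * (seq_len(n1 + 30) - 1),
    x = c(tow$x, loiter$x), y = c(tow$y, loiter$y),
    sog_kn = c(tow$sog_kn, loiter$sog_kn),
    heading_deg = c(tow$heading_deg, loiter$heading_deg),
    lon = 0, lat = 0)
  cls <- classify_behavior(det)
  segs <- activity_segments(cls)
  expect_setequal(segs$label, c("focal", "linear"))
  rec <- daily_rollup(cls, regions, square_site())
  g <- function(cat) {
    r <- rec[rec$region == "inner" & rec$category == cat, ]
    if (nrow(r) == 0) 0L else r$track_count
  }
  expect_equal(g("focal"), 1L)
  expect_equal(g("linear"), 1L)
  expect_equal(g("potential_fishing"), 1L)  # once, not twice
  expect_equal(g("all"), 1L)
  expect_equal(g("non_fishing"), 0L)
})

test_that("count categories reconcile: non_fishing + potential = all", {
  set.seed(31)
  scn <- scenario(n_days = 3, seed = 31, clutter_rate = 0,
                  daily_intensity = c(transit = 4, focal_loiter = 3,
                                      linear_tow = 3))
  sim <- simulate_scenario(scn)
  det <- project_to_planar(sim$detections, sim$site) |>
    clip_to_range(sim$regions) |>
    classify_behavior()
  rec <- daily_rollup(det, sim$regions, sim$site)
  wide <- rec |>
    select(-"track_hours") |>
    tidyr::pivot_wider(names_from = "category", values_from = "track_count",
                       values_fill = 0L)
  expect_true(all(wide$non_fishing + wide$potential_fishing == wide$all))
  # focal/linear double-counting bound
  expect_true(all(wide$potential_fishing <= wide$focal + wide$linear))
  expect_true(all(wide$focal + wide$linear <= 2 * wide$potential_fishing))
})

test_that("region hours are additive within the vicinity", {
  regions <- square_regions()
  set.seed(8)
  scn <- scenario(n_days = 2, seed = 8, clutter_rate = 0)
  sim <- simulate_scenario(scn)
  det <- project_to_planar(sim$detections, sim$site) |>
    clip_to_range(sim$regions) |>
    classify_behavior()
  rec <- daily_rollup(det, sim$regions, sim$site)
  tot <- rec |>
    filter(.data$category == "all") |>
    select("date", "region", "track_hours") |>
    tidyr::pivot_wider(names_from = "region", values_from = "track_hours",
                       values_fill = 0)
  # runs can bridge region changes, so the region split can only lose the
  # bridging intervals, never gain
  expect_true(all(tot$inner + tot$boundary + tot$outer <=
                    tot$vicinity + 1e-9))
  expect_true(all(tot$vicinity <= tot$full_range + 1e-9))
})

test_that("normalisation by area divides and inverts exactly", {
  rec <- tibble(date = as.Date("2019-06-01"), site_id = "s",
                region = c("inner", "vicinity"),
                category = "all", track_count = c(1L, 1L),
                track_hours = c(2, 1.964))
  areas <- tibble(region = c("inner", "vicinity"),
                  area_km2 = c(4, 159.19))
  out <- normalize_by_area(rec, areas)
  expect_equal(out$hours_per_km2, c(0.5, 1.964 / 159.19))
  expect_equal(out$hours_per_km2 * out$area_km2, out$track_hours,
               tolerance = 1e-12)
  expect_equal(normalize_by_area(mutate(rec, track_hours = 0), areas)$hours_per_km2,
               c(0, 0))
  expect_error(normalize_by_area(rec, mutate(areas, area_km2 = c(0, 1))),
               "Non-positive")
})

test_that("grid rollup accumulates resident time per cell", {
  regions <- square_regions()
  grid <- build_grid(regions$polys$vicinity, cell_size_m = 500)
  # parked inside one cell for 600 s
  det <- tibble(track_id = "P", timestamp = t0 + seq(0, 600, 2),
                x = -910, y = 3100, sog_kn = 1, heading_deg = 0,
                behavior = factor("focal", levels = c("focal", "linear", "other")))
  gh <- grid_rollup(det, grid, categories = "all")
  expect_equal(nrow(gh), 1)
  expect_equal(gh$track_hours, 600 / 3600)

  # min-max normalisation maps {0, 2, 4} to {0, 0.5, 1}
  fake <- tibble(track_id = c("a", "b", "c"),
                 timestamp = rep(t0, 3), x = 1, y = 1,
                 sog_kn = 1, heading_deg = 0)
  vals <- tibble(cell_id = 1:3, category = "all", track_hours = c(0, 2, 4))
  norm <- vals |>
    dplyr::group_by(category) |>
    dplyr::mutate(relative = (track_hours - min(track_hours)) /
                    (max(track_hours) - min(track_hours))) |>
    dplyr::ungroup()
  expect_equal(norm$relative, c(0, 0.5, 1))
  gh2 <- grid_rollup(det, grid, categories = "all", normalize = TRUE)
  expect_equal(gh2$relative, 1)
})

test_that("grid hours equal region hours for cell-respecting tracks", {
  regions <- square_regions()
  grid <- build_grid(regions$polys$full_range, cell_size_m = 1000)
  # hop between two cell centres, 300 s in each, never straddling mid-run
  seg <- function(x0, tstart) {
    tibble(track_id = "H", timestamp = t0 + tstart + seq(0, 300, 2),
           x = x0, y = 3100, sog_kn = 1, heading_deg = 0)
  }
  det <- dplyr::bind_rows(seg(-905, 0), seg(95, 400))
  gh <- grid_rollup(det, grid, categories = "all")
  expect_equal(nrow(gh), 2)
  expect_equal(sum(gh$track_hours), 600 / 3600)
})

test_that("summary tables reproduce printed-table arithmetic", {
  mk <- function(site, count_all, count_pf, hours_all, hours_pf) {
    tibble(date = as.Date("2019-06-01"), site_id = site,
           region = "full_range",
           category = c("all", "potential_fishing"),
           track_count = c(count_all, count_pf),
           track_hours = c(hours_all, hours_pf))
  }
  rec <- dplyr::bind_rows(
    mk("piedras_blancas", 2407L, 968L, 1346, 618),
    mk("campus_point", 14136L, 2960L, 4259, 1578),
    mk("south_la_jolla", 15347L, 7994L, 4220, 1949))
  st <- summary_tables(rec)
  ov <- st[st$site_id == "overall", ]
  expect_equal(ov$count_sum[ov$category == "all"], 31890L)
  expect_equal(ov$count_sum[ov$category == "potential_fishing"], 11922L)
  expect_equal(ov$count_pct[ov$category == "potential_fishing"], 37)
  expect_equal(ov$hours_sum[ov$category == "all"], 9825)
  expect_equal(ov$hours_sum[ov$category == "potential_fishing"], 4145)
  expect_equal(ov$hours_pct[ov$category == "potential_fishing"], 42)
  # per-site percentages as printed
  ps <- st[st$site_id == "piedras_blancas" &
             st$category == "potential_fishing", ]
  expect_equal(ps$count_pct, 40)
  expect_equal(ps$hours_pct, 46)
})

test_that("daily means include zero days and a single day has sd 0", {
  rec <- tibble(date = as.Date("2019-06-01"), site_id = "s",
                region = "full_range", category = "all",
                track_count = 5L, track_hours = 2)
  st <- summary_tables(rec)
  expect_equal(st$count_daily_mean[st$site_id == "s"], 5)
  expect_equal(st$count_daily_sd[st$site_id == "s"], 0)

  # with declared analysis days, empty days count as zeros
  st2 <- summary_tables(rec, analysis_days = list(
    s = as.Date("2019-06-01") + 0:4))
  expect_equal(st2$count_daily_mean[st2$site_id == "s"], 1)
  expect_equal(st2$n_days[st2$site_id == "s"], 5)
})
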