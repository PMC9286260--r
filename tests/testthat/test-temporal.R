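# Independent ephemeris oracle: Astronomical Almanac low-precision solar
# position (right ascension / declination / hour angle formulation) with
# numeric root-finding of the -0.833 degree altitude crossing. Entirely
# separate from the closed-form hour-angle implementation under test.
solar_alt_oracle <- function(t_utc, lat, lon) {
  n <- as.numeric(julian(t_utc,
                         origin = as.POSIXct("2000-01-01 12:00:00", tz = "UTC")))
  L <- (280.460 + 0.9856474 * n) %% 360
  g <- (357.528 + 0.9856003 * n) %% 360
  lam <- L + 1.915 * sin(g * pi / 180) + 0.020 * sin(2 * g * pi / 180)
  eps <- 23.439 - 0.0000004 * n
  ra <- atan2(cos(eps * pi / 180) * sin(lam * pi / 180),
              cos(lam * pi / 180)) * 180 / pi
  dec <- asin(sin(eps * pi / 180) * sin(lam * pi / 180))
  gmst <- (18.697374558 + 24.06570982441908 * n) %% 24 * 15
  H <- ((gmst + lon - ra + 180) %% 360) - 180
  asin(sin(lat * pi / 180) * sin(dec) +
         cos(lat * pi / 180) * cos(dec) * cos(H * pi / 180)) * 180 / pi
}

oracle_rise_set_utc <- function(date, lat, lon) {
  day0 <- as.POSIXct(paste(date, "00:00:00"), tz = "UTC")
  f <- function(h) solar_alt_oracle(day0 + h * 3600, lat, lon) + 0.833
  hs <- seq(0, 24, by = 0.05)
  alts <- sapply(hs, function(h) solar_alt_oracle(day0 + h * 3600, lat, lon))
  noon <- hs[which.max(alts)]
  c(rise = uniroot(f, c(noon - 12, noon))$root,
    set = uniroot(f, c(noon, noon + 12))$root)
}

test_that("sunrise/sunset behave physically and match the ephemeris oracle", {
  # equator at equinox: roughly 12 h day centred on local noon
  st <- sun_times(as.Date("2019-03-20"), lat = 0, lon = 0, utc_offset = 0)
  rise_h <- as.numeric(format(st$sunrise, "%H")) +
    as.numeric(format(st$sunrise, "%M")) / 60
  set_h <- as.numeric(format(st$sunset, "%H")) +
    as.numeric(format(st$sunset, "%M")) / 60
  # refraction and the solar radius stretch the day ~3-4 min at each end,
  # and the equation of time shifts noon by several minutes in March
  expect_lt(abs(rise_h - 6), 12 / 60)
  expect_lt(abs(set_h - 18), 12 / 60)

  # mid-northern summer day exceeds 12 h
  st2 <- sun_times(as.Date("2019-06-21"), lat = 34, lon = -120,
                   utc_offset = -8)
  expect_gt(as.numeric(difftime(st2$sunset, st2$sunrise, units = "hours")), 12)

  # randomized cross-check against the independent oracle, within 2 min
  set.seed(3)
  for (i in 1:20) {
    d <- as.Date("2019-01-01") + sample(0:364, 1)
    lat <- runif(1, -55, 55); lon <- runif(1, -180, 180)
    o <- oracle_rise_set_utc(d, lat, lon)
    st <- sun_times(d, lat, lon, utc_offset = 0)
    day0 <- as.POSIXct(paste(d, "00:00:00"), tz = "UTC")
    rise_h <- as.numeric(difftime(st$sunrise, day0, units = "hours"))
    set_h <- as.numeric(difftime(st$sunset, day0, units = "hours"))
    expect_lt(abs((rise_h - o["rise"] + 12) %% 24 - 12) * 60, 2)
    expect_lt(abs((set_h - o["set"] + 12) %% 24 - 12) * 60, 2)
  }

  expect_error(sun_times(as.Date("2019-06-21"), lat = 70, lon = 0), "polar")
})

test_that("track tags use the first point's local time", {
  # 2019-06-01 21:05 UTC = 13:05 local (UTC-8) on Saturday June 1st
  det <- straight_track("T1", 5, 4, 90,
                        t0 = as.POSIXct("2019-06-01 21:05:00", tz = "UTC"))
  tags <- tag_tracks(det, square_site())
  expect_equal(as.character(tags$day_of_week), "Saturday")
  expect_equal(tags$hour_of_day, 13)
  expect_true(tags$is_weekend)
  expect_equal(tags$start_day, as.Date("2019-06-01"))

  # Monday is a weekday
  det2 <- straight_track("T2", 5, 4, 90,
                         t0 = as.POSIXct("2019-06-03 18:00:00", tz = "UTC"))
  expect_false(tag_tracks(det2, square_site())$is_weekend)
})

test_that("every point is exactly one of day or night", {
  site <- square_site()
  # local noon and local 23:30
  det <- dplyr::bind_rows(
    straight_track("noon", 3, 4, 90,
                   t0 = as.POSIXct("2019-06-01 20:00:00", tz = "UTC")),
    straight_track("night", 3, 4, 90,
                   t0 = as.POSIXct("2019-06-01 07:30:00", tz = "UTC")))
  tagged <- tag_day_night(det, site)
  expect_type(tagged$is_day, "logical")
  expect_false(anyNA(tagged$is_day))
  expect_true(all(tagged$is_day[tagged$track_id == "noon"]))
  expect_false(any(tagged$is_day[tagged$track_id == "night"]))
})

test_that("season calendars round-trip through YAML and evaluate state", {
  cal <- season_calendar(tibble(
    fishery_id = c("lobster", "tow_fishery"),
    pattern = c("focal", "linear"),
    sites = list("sq", "sq"),
    open = list(
      tibble(start = as.Date(c("2019-01-01", "2019-10-01")),
             end = as.Date(c("2019-03-15", "2019-12-31"))),
      tibble(start = as.Date("2019-06-01"), end = as.Date("2019-08-31")))
  ))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_season_calendar(cal, path)
  back <- read_season_calendar(path)
  expect_equal(back$fisheries$fishery_id, cal$fisheries$fishery_id)
  expect_equal(back$fisheries$open[[1]], cal$fisheries$open[[1]])

  expect_equal(season_state(as.Date(c("2019-02-01", "2019-05-01",
                                      "2019-10-01")), cal, "lobster"),
               c("open", "closed", "open"))
  expect_error(season_state(as.Date("2019-02-01"), cal, "nope"), "Unknown")
  # overlapping intervals are rejected
  expect_error(season_calendar(tibble(
    fishery_id = "bad", pattern = "focal", sites = list("sq"),
    open = list(tibble(start = as.Date(c("2019-01-01", "2019-02-01")),
                       end = as.Date(c("2019-03-01", "2019-04-01")))))),
    "overlap")
})

test_that("quantile test matches hand-computed hypergeometric cases", {
  qt <- quantile_test(c(1, 2, 3), c(10, 11, 12), alternative = "greater")
  expect_equal(qt$pooled_quantile, 3)
  expect_equal(qt$t_obs, 3)
  expect_equal(qt$a_obs, 3)
  expect_equal(qt$p_value, choose(3, 3) * choose(3, 0) / choose(6, 3))

  # all tied: no separation, p = 1
  expect_equal(quantile_test(c(5, 5), c(5, 5))$p_value, 1)

  # exchanging samples with the flipped alternative gives the same p
  set.seed(13)
  x <- rlnorm(6); y <- rlnorm(5, meanlog = 0.4)
  expect_equal(quantile_test(x, y, alternative = "greater")$p_value,
               quantile_test(y, x, alternative = "less")$p_value)

  expect_error(quantile_test(numeric(0), 1:3), "non-empty")
  td <- tidy(quantile_test(x, y))
  expect_equal(td$p.value, quantile_test(x, y)$p_value)
  expect_equal(td$m, 6)
})

test_that("quantile test equals exhaustive permutation enumeration", {
  set.seed(77)
  for (rep in 1:30) {
    m <- sample(1:7, 1); n <- sample(1:7, 1)
    if (rep %% 2 == 0) {
      # heavy ties
      x <- sample(1:3, m, replace = TRUE)
      y <- sample(1:3, n, replace = TRUE)
    } else {
      x <- round(rlnorm(m), 2); y <- round(rlnorm(n, 0.5), 2)
    }
    for (alt in c("greater", "less")) {
      expect_equal(quantile_test(x, y, alternative = alt)$p_value,
                   permutation_quantile_p(x, y, alternative = alt),
                   tolerance = 1e-12,
                   info = sprintf("m=%d n=%d alt=%s rep=%d", m, n, alt, rep))
    }
  }
})

test_that("p-value is monotone under upward shifts of the open sample", {
  set.seed(55)
  x <- rlnorm(12); y <- rlnorm(12)
  ps <- sapply(c(0, 0.5, 1, 2, 4), function(s) {
    quantile_test(x, y + s, alternative = "greater")$p_value
  })
  expect_true(all(diff(ps) <= 1e-12))
})

test_that("season comparison tests open>closed and reports skips", {
  cal <- season_calendar(tibble(
    fishery_id = "lobster", pattern = "focal", sites = list("sq"),
    open = list(tibble(start = as.Date("2019-07-01"),
                       end = as.Date("2019-12-31")))))
  set.seed(17)
  days <- as.Date("2019-01-01") + 0:363
  open <- season_state(days, cal, "lobster") == "open"
  rec <- tibble(
    date = days, site_id = "sq", region = "boundary", category = "focal",
    track_count = 1L, track_hours = 1,
    hours_per_km2 = rlnorm(length(days),
                           meanlog = ifelse(open, log(2), 0), sdlog = 0.6))
  res <- season_comparison(rec, cal, regions_tested = "boundary",
                           strata = "all")
  expect_equal(nrow(res), 1)
  expect_false(res$skipped)
  expect_lt(res$p_value, 0.001)
  expect_equal(res$stars, "***")
  expect_gt(res$median_open, res$median_closed)

  # empty closed side -> skipped combination, recorded not dropped
  rec2 <- rec[open, ]
  res2 <- season_comparison(rec2, cal, regions_tested = "boundary",
                            strata = "all")
  expect_true(res2$skipped)
  expect_equal(res2$m, 0)
  expect_true(is.na(res2$p_value))

  # weekday/weekend strata partition the days
  res3 <- season_comparison(rec, cal, regions_tested = "boundary",
                            strata = c("weekday", "weekend"))
  expect_equal(nrow(res3), 2)
  expect_equal(sum(res3$m) + sum(res3$n), nrow(rec))
})

test_that("zero-activity days are ignored in season tests", {
  cal <- season_calendar(tibble(
    fishery_id = "f", pattern = "linear", sites = list("sq"),
    open = list(tibble(start = as.Date("2019-07-01"),
                       end = as.Date("2019-12-31")))))
  days <- as.Date("2019-06-25") + 0:9
  rec <- tibble(date = days, site_id = "sq", region = "outer",
                category = "linear", track_count = 1L, track_hours = 1,
                hours_per_km2 = c(0, 0, 1, 2, 3, 0, 4, 5, 6, 0))
  res <- season_comparison(rec, cal, regions_tested = "outer", strata = "all")
  expect_equal(res$m, 3)   # 3 positive closed days
  expect_equal(res$n, 3)   # 3 positive open days
})
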