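Package: mpatrack
Title: Radar-Based Monitoring of Vessel Activity Near Marine Protected Areas
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for shore-based marine radar tracking of
    vessels in the vicinity of marine protected areas (MPAs). Provides quality
    control for radar detection streams (deduplication, range clipping,
    maintenance-day and log-count outlier day exclusion, rule-based false-target
    screening), rolling-window kinematic classification of detection points into
    focal (loitering / manoeuvring) and linear (slow steady tow) activities of
    interest, MPA region geometry (vicinity, inner, boundary, outer) with
    gridded effort surfaces, activity metrics (daily track counts, cumulative
    track hours, area-normalised activity), temporal attribution (day/night by
    solar position, weekday/weekend, fishing-season state) and the exact
    two-sample quantile test for closed/open season comparisons. A trajectory
    simulator with ground-truth behaviour labels supports end-to-end testing
    without access to radar hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lubridate,
    polyclip,
    purrr,
    rlang,
    readr,
    sp,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    geosphere,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
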