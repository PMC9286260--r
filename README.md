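# mpatrack

Vessel-activity monitoring around marine protected areas (MPAs) from
shore-based marine radar tracks.

Nearshore MPAs are hard to police: most small vessels carry no AIS or VMS
transponder, so compliance has to be inferred from non-participatory
sensors. An onshore X-band radar produces a stream of timestamped detection
points (position, speed over ground, heading, track id) at roughly 2-second
resolution. `mpatrack` turns such streams into defensible activity
measures for the waters around an MPA: who was where, for how long, doing
what, and whether "fishing the line" intensifies when a season opens. It is
aimed at MPA managers, enforcement analysts, and movement ecologists
working with radar (or radar-like) vessel trajectories.

## What it computes

**Quality control.** Duplicate removal, range clipping to the reliable
detection radius (5 nmi = 9,260 m), exclusion of maintenance days ±1 day,
exclusion of days whose log daily track count falls more than 2 SD from
the site mean, and rule-based screening of sea-clutter false targets
(pluggable: supply your own classifier over per-track features).

**Behaviour classification.** Each detection point gets rolling-window
kinematics over the preceding k = 12 points: mean speed s̄, circular mean
heading θ̄, heading deviation Δθ = |θ − θ̄| (wrapped), relative speed
deviation |s − s̄| / s̄. Points are labelled

- **focal** (loitering / manoeuvring; proxy for trapping or hook-and-line):
  s < 2 kn, or 2 ≤ s ≤ 6 kn with Δθ ≥ 15°;
- **linear** (slow steady tow; proxy for trawling or trolling):
  2 ≤ s ≤ 6 kn, Δθ < 15°, |s − s̄| / s̄ < 0.25;
- **other** (including transit at > 6 kn).

Runs of ≥ 12 identically labelled points become activity segments;
shorter runs are demoted.

**Geometry.** An azimuthal-equidistant planar workspace centred on the
radar; the MPA **vicinity** (interior + 1-km outward buffer), the 200-m
**boundary** band centred on the MPA boundary line, the **inner**/**outer**
remainders, and a 246-m analysis grid (~0.06 km² cells), all clipped to
the detection range.

**Metrics and statistics.** Per analysis day, region and category: distinct
track counts, cumulative track hours (concurrent tracks add), and
area-normalised hours per km²; summary tables with daily means ± SD and
whole-percent shares; day/night (NOAA solar equations), weekday/weekend
and fishing-season attribution; and the exact two-sample quantile test
(q = 0.5): with ξ̂ the pooled median, T = #{pooled ≤ ξ̂} and
A = #{closed-season values ≤ ξ̂}, A is hypergeometric under the null and
P(A ≥ a_obs) tests for greater open-season activity.

**Simulator.** `scenario()`/`simulate_scenario()` generate radar-like
detection streams with ground-truth labels — transit, focal-loiter,
linear-tow archetypes, sea clutter, log-normal day effects, maintenance
days, boundary-biased effort — so the full pipeline is testable end to end.

## Worked example

```r
library(mpatrack)
library(dplyr)

sim <- simulate_scenario(scenario(
  n_days = 4, seed = 42, clutter_rate = 2,
  daily_intensity = c(transit = 3, focal_loiter = 2, linear_tow = 2)))

det <- sim$detections |>
  project_to_planar(sim$site) |>
  dedupe_detections() |>
  clip_to_range(sim$regions)

det <- det |>
  remove_false_targets(screen_false_targets(det)) |>
  classify_behavior()

records <- daily_rollup(det, sim$regions, sim$site) |>
  normalize_by_area(sim$regions)
summary_tables(records) |>
  filter(site_id == "demo", region == "full_range") |>
  select(category, count_sum, count_daily_mean, hours_sum, count_pct)
#> # A tibble: 5 × 5
#>   category          count_sum count_daily_mean hours_sum count_pct
#>   <chr>                 <int>            <dbl>     <dbl>     <dbl>
#> 1 all                      40            10        18.0        100
#> 2 non_fishing              15             3.75      3.95        38
#> 3 potential_fishing        25             6.25     14.1         63
#> 4 focal                    15             3.75      8.61        38
#> 5 linear                   10             2.5       5.44        25
```

Reading: over 4 simulated days the radar saw 40 tracks (10/day); 25 of
them (63% of all observed) showed an activity of interest, split 15 focal
/ 10 linear (a track can hold both patterns), and the 18 cumulative
track hours split 14.1 potential-fishing vs 3.9 likely non-fishing.
`non_fishing + potential_fishing = all` holds by construction for counts.

Region geometry and seasonal tests follow the same grammar:

```r
regions <- build_regions(site)            # vicinity / inner / boundary / outer
assign_region(det, regions)               # per-point region labels
grid_rollup(det, build_grid(regions))     # 246-m effort surface
season_comparison(records, calendar)      # exact quantile tests + stars
```

A thin command-line front end wraps the same functions:
`inst/cli/mpatrack.R simulate|run|regions|test-seasons`.

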