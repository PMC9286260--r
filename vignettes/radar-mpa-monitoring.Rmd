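---
title: "Methods: radar-based vessel activity around MPA boundaries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: radar-based vessel activity around MPA boundaries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpatrack)
library(dplyr)
```

## The measurement problem

A shore-based marine radar reports detection points — timestamp, position,
speed over ground (SOG), heading, track id — for every target it can hold,
typically every 2 seconds. Unlike AIS/VMS, there is no vessel identity and
no declared activity, so fishing effort must be inferred from trajectory
shape, and the data carry radar-specific artefacts: sea-clutter false
tracks, fragmentation of one vessel into several track ids, and whole days
degraded by weather or system maintenance. `mpatrack` implements a
pipeline that addresses each artefact explicitly and then measures
activity with three complementary metrics (track counts, cumulative track
hours, hours per km²) in a set of management-relevant regions around an
MPA.

## Planar workspace

All distances in the analysis are metric (1-km vicinity buffer, 200-m
boundary band, 246-m cells, 9,260-m range clip), so detections are
projected into an azimuthal-equidistant plane centred on the radar, built
on a sphere of radius 6,371,008.8 m (IUGG mean). Two properties motivate
this choice: distance from the projection centre is preserved exactly, so
the range clip is a true disc; and the closed-form inverse makes
round-trips exact to machine precision (the suite checks < 1e-6°). Over a
9.3-km working radius the spherical-vs-ellipsoidal discrepancy is far
below the radar's own positional noise.

## Region model

The MPA **vicinity** is read as the MPA interior *plus* a 1-km outward
dilation, not as a two-sided band around the boundary line. The published
per-site inner-region areas (e.g. 38.06 km² at the largest site) are much
larger than any 1-km band could contain, which settles the reading; the
two interpretations are one flag apart in `build_regions()` if a band is
ever wanted. The **boundary** region is the band within 100 m of the MPA
outline on each side (200 m total). **Inner** and **outer** are the
remainders inside/outside the MPA; all regions are intersected with the
**full range** (detection disc minus user-supplied exclusion polygons —
coastline masks are data, not model).

Offsets use round joins, the standard buffer semantics: a convex corner of
the MPA contributes a circular arc, so a square of side `a` buffered by
`w` has area `a² + 4aw + πw²` — the identity the geometry suite asserts.
Polygon booleans run through the Clipper library (`polyclip`) with the
integer-scaling resolution set to 1e-8 m, which keeps the
inner + boundary + outer = vicinity partition and grid-area conservation
well inside 1e-6 relative error. Points exactly on shared edges are
assigned by the fixed precedence boundary > inner > outer, so labelling is
deterministic for measure-zero cases.

The analysis grid is an axis-aligned 246-m lattice (cells ~0.06 km²; the
cell size is a parameter — it stands in for a positional-error scale that
is site- and hardware-specific) anchored at the lower-left corner of the
extent's bounding box; no datum-specific anchoring is attempted since none
is defined for the original deployments.

## Quality control

*Deduplication* collapses rows identical in (track, time, position) and
drops rows with missing attributes; parsing failures are collected into a
reject report with line numbers rather than silently dropped.

*Day filter.* Tracks are attributed to the local calendar day (fixed site
UTC offset, no DST — the "day" of interest is the civil day at the site)
of their first detection. Maintenance days and their immediate neighbours
are excluded; then, on the remaining observed days, days with
|ln(count) − mean| > 2 SD are excluded. The natural log is used: the
z-scores, and hence the excluded set, are identical under any log base, so
the choice is cosmetic. Outlier statistics are computed *after*
maintenance removal, mirroring the stated order of operations. With fewer
than 3 remaining days the SD is unstable and the outlier step is skipped
with a warning. A subtlety the tests document: with very short series a
single extreme day inflates the SD enough to mask itself (a 5-day series
with counts {20, 22, 19, 21, 400} excludes nothing at 2 SD — z ≈ 1.8),
which is the expected behaviour of the rule, not a defect.

*False-target screening.* The original deployments used a trained
classifier whose internals and training data are not reproducible; the
package therefore exposes a pluggable screener over per-track features
(duration, point count, median SOG, net displacement, straightness, mean
absolute turn) and ships a rule surrogate: false target iff fewer than 12
points, or shorter than 30 s, or essentially stationary and tortuous
(straightness < 0.05 and median SOG < 0.5 kn). Clutter returns are short
and erratic with near-zero net displacement, which is exactly what these
rules cut. A screener failure labels tracks *vessel* and flags them —
failing open so real vessels are never silently discarded. The ≥ 90%
accuracy asserted in the tests is a property of the synthetic fixtures,
not a claim about any real radar.

## Behaviour rules

For point *i*, the window is the preceding *k* = 12 points, excluding the
current one; `window_full` requires all 12. The preceding-average heading
is the *circular* mean (unit-vector average): an arithmetic mean of
headings is simply wrong across north (350° and 10° average to 180°), and
the rules' heading-deviation term must be wrap-safe. The decision order
is:

1. SOG < 2 kn → focal (applies even without a full window — slowness
   needs no history);
2. 2–6 kn, full window, heading deviation ≥ 15° → focal;
3. 2–6 kn, full window, deviation < 15°, relative speed deviation
   < 0.25 → linear;
4. otherwise other.

The speed band is in knots and inclusive; metre-per-second equivalents
seen in prose are rounded conversions and are not used. Warm-up points
(no full window) can only be focal via rule 1 — the conservative reading,
since no warm-up rule is defined. When the preceding mean speed is zero
the relative deviation is undefined and treated as +∞ (rule 4), a
division guard. Focal and linear are mutually exclusive by construction;
a *track* may still hold both patterns in different segments and then
counts once in each category and once in potential fishing.

Only runs of ≥ 12 identically labelled focal/linear points become
activity segments; shorter runs are demoted to other for all downstream
activity-of-interest computations.

## Activity metrics

*Counts.* A track counts in a (day, region, category) cell if it has at
least one qualifying point there; fragmentation means counts are an upper
bound on unique vessels, which is inherent to radar and left uncorrected.

*Hours.* Within a spatial unit, duration is summed over *maximal runs* of
consecutive in-unit points (first-to-last time per run). The alternative —
one interval from first to last in-unit point — would charge a track for
time spent outside a unit it re-enters, so the run-based reading is used;
for tracks that never exit, the two coincide. Single-point runs are
presence with zero duration, which is why counts and hours are
deliberately decoupled. Hours add across concurrent tracks: cumulative
pressure on an area is the quantity of interest, so > 24 h per day is
meaningful, not an error.

*Normalisation.* Hours per km² divides by the region's area, making sites
and regions of different size comparable; the inverse
(`hours_per_km2 × area = hours`) is exact by construction.

*Summaries.* Per site and overall: sums over analysis days, daily
means ± SD (days without a record count as zero when the analysis-day set
is supplied), and whole-number percentages of the all-observed full-range
total, rounded half away from zero — the convention that reproduces every
printed percentage in the reference tables.

## Temporal statistics

Track-level day-of-week/hour tags come from the first detection;
point-level day/night from NOAA's solar-position equations (zenith
90.833°, i.e. refraction plus solar radius) at the site coordinates —
cross-checked in the suite against an independent altitude-root-finding
ephemeris to within 2 minutes. Latitudes beyond ±66° are rejected rather
than approximated. Season calendars (fishery → open intervals, pattern,
sites) are user configuration, since season dates are regulatory data.

Daily activity is strongly zero-inflated and not usefully transformable to
normality, so season comparisons use the exact two-sample quantile test at
q = 0.5. The convention fixed here: pooled quantile ξ̂ = order statistic
of rank ⌈qN⌉; T = #{pooled ≤ ξ̂} (ties count at-or-below);
A = #{closed ≤ ξ̂}; A ~ Hypergeometric(N, m, T) under exchangeability;
the open-greater p-value is P(A ≥ a_obs), two-sided is twice the smaller
tail capped at 1. Any such test needs a tie/rank convention; this one is
validated in the suite by *exhaustive permutation enumeration* for all
m, n ≤ 7, with and without ties, so the convention and the distribution
agree exactly. Zero-activity days are removed before testing, and the
alternative is one-sided open > closed throughout, matching how seasonal
effects are reported. Combinations with an empty side are reported as
skipped rather than tested.

## What the simulator emulates — and what it does not

`simulate_scenario()` generates: correlated-random-walk tracks from three
archetypes placed firmly inside the classification thresholds (transit
> 6 kn; focal-loiter < 1.8 kn with 40°/step turn noise; linear-tow
3.5 ± 0.1 kn with 1°/step turn noise), 2-s sampling, Gaussian positional
jitter (default SD 5 m — positional error is a free parameter here, not a
physical radar model), small measurement noise on recorded SOG/heading,
Poisson daily counts modulated by a log-normal day effect (so the 2-SD
day filter has real work to do), short erratic clutter tracks, tracks on
maintenance days, optional boundary-biased focal starts ("fishing the
line") and optional open-season intensity multipliers. Everything is
reproducible from one seed.

It does *not* emulate: radar shadowing or sea-state physics, track
fragmentation by the tracker, kayaks and other low-profile craft, real
coastlines, or behaviourally ambiguous vessels (slow sailboats look
linear to any rule set). Passing closed-loop tests therefore demonstrates
that the pipeline recovers the behaviours it defines, under the noise
model stated — not that the heuristics are correct for any particular
real fishery.

Archetype parameters sit well inside the thresholds on purpose: recovery
tests should probe the pipeline, not the generator's marginal cases.
Near-threshold behaviour is exercised separately by randomized-rule tests
against a brute-force reimplementation.

## Problem sizes and numerical choices

The shipped suite runs scenarios of 2–6 days at a few tracks per day
(10³–10⁵ points), 1,000 random tracks for the classifier-vs-brute-force
identity, 10⁴ random points for region-assignment agreement, 1,000
null replicates (size) and 200 alternative replicates (power) for the
quantile test, and 8–10 random star-shaped MPAs for the geometry
partition — sizes chosen so the whole suite completes in about two
minutes while every assertion retains comfortable margin. Key numerical
settings: Clipper resolution 1e-8 m; buffer arc tolerance `delta`/5000;
partition tolerance 1e-6 relative; grid-conservation tolerance 1e-9
relative; solar accuracy 2 min.

## Known limitations

- Track counts overestimate unique vessels under fragmentation; no
  re-identification is attempted.
- Hours between a qualifying and a non-qualifying point are dropped from
  both categories, so focal + linear hours can fall slightly short of
  potential-fishing hours on mixed tracks.
- Fixed UTC offsets ignore DST; if local clock days matter across a DST
  change, supply the offset that defines the study's "day".
- The rule surrogate screener is not the original trained classifier and
  should be re-tuned (or replaced via the pluggable interface) for new
  hardware or sea states.
- Season effects are binary open/closed; within-season dynamics,
  holidays and weather confounders are out of scope.
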