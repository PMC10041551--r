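---
title: "Models and methods behind foxmove"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind foxmove}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(foxmove)
```

foxmove implements a complete desk-scale analysis of daily fox
telemetry: residency vs dispersal classification, a-LoCoH utilization
distributions, excursion and sea-ice commuting detection, survival
table construction and permutation tests, together with a synthetic
trajectory generator that stands in for field data. This vignette
documents the models, the tunable parameters, the numerical choices,
and what the tests do and do not establish.

## Seasons and track resolution

Two seasons partition the year: summer (May 15 – October 31, the
goose-driven period of food abundance on the coastal tundra) and
winter (November 1 – May 14, the scarcity period). Winter instances
are labelled by the year of their November 1 and wrap the year end.
All analyses run at one fix per day: collars duty-cycle unevenly, so
tracks are thinned by keeping one uniformly random fix per local
calendar day (UTC−6 day boundaries by default). Thinning is
idempotent, and each animal draws from an RNG stream derived from the
master seed and its id, so adding an animal never changes another's
thinning.

## a-LoCoH utilization distributions

For each fix, neighbours are added in increasing Euclidean distance
while their cumulative distance stays within the adaptive radius *a*
(the time-scaling exponent is fixed at 0, so time-scaled distance
reduces to plain distance). Each local hull is the convex hull of the
root and its neighbours; degenerate hulls (fewer than three distinct
points) are kept with zero area. Hulls sorted by ascending area (ties:
more enclosed points, then root index) are unioned until the union
covers `ceiling(level * n)` fixes; boundary points count as covered.
Nesting across levels holds by construction because lower levels are
prefixes of higher ones.

Union and intersection **areas are exact**: the plane is cut at every
edge endpoint and edge crossing, within a slab every covered-interval
endpoint is linear in x, and 2-point Gauss–Legendre integrates the
covered length and its moments exactly up to floating point (compiled
code; a pure-R twin of the algorithm is kept as a test oracle). This
is why isopleth areas are invariant under rotation and translation to
~1e-12 relative, something rasterized areas cannot promise.

**Choosing a.** The interactive graph-tool selection used in field
workflows is not reproducible, so the package substitutes a stated
rule: *a* is a quantile of pairwise inter-fix distances, default the
maximum. Two consequences worth knowing:

* With *a* = max pairwise distance the local hulls remain *local* —
  the cumulative-distance budget is exhausted after a handful of
  neighbours. The union of such hulls on points in convex position is
  a thin ring, **not** the global convex hull; the full-data convex
  hull is only recovered once *a* is large enough that every hull
  contains every point. Tests that assert hull equality therefore use
  a very large *a*; at *a* = max pairwise distance the 100% isopleth
  of 500 uniform points in the unit square covers about 0.90, at large
  *a* about 0.97 (the convex hull of the sample).
* The maximum-distance rule is fragile under excursions: one far
  commuting bout stretches *a* until the 95% isopleth swallows parts
  of the excursion corridor. The excursion analysis therefore refits
  the UD once from the fixes below a pinned log-scale Hampel bound
  before detecting trips (skipped when more than 20% of fixes would
  drop). This mirrors the field practice of tuning *a* to "exclude
  unused areas", and the pipeline reports the refined ranges.

**Seasonal shift.** A single published "overlap %" is ambiguous, so
both directional fractions (intersection over each season's area),
their mean (the default summary), and intersection-over-union are all
reported, alongside the distance between the 95%-isopleth area
centroids.

**Area asymptote.** The 95% area is recomputed on growing prefixes;
the asymptote is the smallest prefix length whose area stays within
±5% of the full-data area for all larger prefixes. Because hull-union
areas of a stationary cloud keep growing gently with sample size, the
asymptote under this explicit rule sits later (n ≈ 83 of 100 on the
bundled OU fixture) than the n ≈ 38 that interactive hand-tuned-a
workflows report; tracks shorter than 38 fixes are classed
"insufficient" either way.

## Residency, dispersal, survival

An animal-season is **resident** if it has at least 38 fixes, no
dispersal is segmented, and the centroids of the two track halves are
closer than the 95%-range diameter (nondirectional movement). A
**dispersal** starts at the last fix inside the prior 95% isopleth
before a departure that never returns (or at the first fix when no
prior range exists — an animal collared while dispersing); it ends at
the first fix of the earliest window of more than 7 days (≥ 8 calendar
days, at most one gap day) on land whose fixes stay within 5 km of
their centroid, else at death or track end. Two thresholds the source
workflow left implicit are explicit, logged settings here: the
departing run must last ≥ 3 days and end ≥ 10 km from the prior range
centroid — without them a resident's last out-of-isopleth fix before a
season boundary would count as "never returned".

The prior range for a season is the previous resident season's UD when
available, else it is estimated from the season's first 38 fixes; if
that prefix itself drifts (half-centroid displacement exceeding half
the prefix diameter), the animal is treated as collared mid-dispersal.

Season of capture is excluded from tactic and range comparisons
(residency before capture is unobservable), but dispersal events and
survival records from the capture season are kept — dispersals are
characterised wherever they occur.

The survival table is time since November 1, an event row for a death
inside the winter window, censoring at May 14 or at the last fix.
Model fitting is deliberately out of scope; the table feeds any
external Cox implementation.

## Excursions and commuting

Trips are maximal runs of consecutive fixes outside the 95% isopleth,
bracketed by in-range fixes (a run still open at track end never
returned and is discarded). Only the trip's **farthest** fix is tested
against the Hampel bound: upper bound = median + 3 MAD of the
transformed distances to the 95%-isopleth centroid, computed per
animal-season over all of that season's fixes. A trip is an excursion
when its farthest distance exceeds the bound and it lasts under 7
days; an excursion with any fix on sea ice is a commuting trip; all
other trips are border movements. Frequencies are counts per 7 tracked
days, reported for land excursions alone and for excursions plus
commuting.

"Tukey-transformed" names no exponent, so the package selects one from
the ladder {−1, −1/2, 0 (log), 1/3, 1/2, 1} by maximizing
normal-quantile correlation — computed on the lower 95% of the sample,
because otherwise the very outliers the filter must catch drive the
selection toward strong negative exponents whose bound can be vacuous
(for λ < 0 the transform maps onto (−∞, 0); a bound at or above 0
corresponds to an infinite raw threshold, which the implementation
returns honestly). The transform can be pinned (e.g. to log) via
configuration. The MAD is raw (unscaled) by default — the rule says "3
median absolute deviations", not 3 robust standard deviations; with
the optional 1.4826 consistency factor the bound sits at 3 SD on the
transformed scale, and on a 200-point lognormal sample with five
planted 10× outliers it flags exactly the planted points, whereas the
raw-MAD bound (~2 SD) additionally flags ~2% of the bulk by
construction.

## Permutation tests

Two-sided t-statistic permutation tests, Welch form by default (pooled
available). Whenever the number of distinct relabellings (or sign
patterns, paired case) is at most `n_perm`, the full set is enumerated
and p is the exact proportion including the identity; otherwise
p = (1 + #{|t*| ≥ |t|}) / (n_perm + 1) over `n_perm` seeded draws.
Complete-separation splits (both groups constant, different means)
yield t = ±Inf and are kept; 0/0 splits carry no evidence and count as
zero. No multiplicity correction is applied, matching the single-test
reporting style of the source analyses (α = 0.1 is annotated, nothing
more).

## The synthetic world

The default world is a 6000 × 6000 km plane: a 200 km tundra band
along a straight east–west coastline, sea to the north (ice available
December 2 – July 7, wrapping), boreal forest to the south. Habitat is
assigned by point-in-polygon with land priority on boundaries; sea
fixes outside the ice window are flagged implausible.

**Residents** follow a daily Ornstein–Uhlenbeck walk,
x(t+1) = μ + φ(x(t) − μ) + ε with φ = exp(−reversion). The default
reversion of 1/day encodes that a fox patrols its whole range within a
day or two, so successive daily fixes are nearly independent samples
of the utilization distribution. The stationary spread is set from the
season's target 95% area: the bivariate-normal 95% ellipse has area
π χ²₀.₉₅,₂ σ², and the a-LoCoH estimate of an n-fix OU cloud
undershoots that ellipse by a factor that grows with n (the hull union
of a finite sample cannot reach the ellipse boundary). That factor was
measured by Monte Carlo (24 replicates per point at n = 60–300,
reversion 1/day) and frozen as a log-n-interpolated table; with it,
the median estimated/target area ratio is 1.00 at n ∈ {100, 170, 300}
and the median relative error is 5–10%, so the calibration tolerance
asserted in the acceptance tests is 15%. Season targets default to the
field-scale values: ~16–18 km² summer ranges in both species, winter
~35 km² (red-like expansion) vs ~20 km² (Arctic-like constancy).

**Excursion bouts** start with per-day probability rate/7 (defaults:
red 0.05/week summer, 0.13 winter; Arctic 0.08 and 0.06, with
commuting at 0.15/week inside the ice window only), last 1–3 days
(< 7 by constraint), and follow a triangular out-and-back profile that
always touches an apex at 3–4× the stationary range radius — landward
for excursions, beyond the coastline for commuting. All bouts are
recorded as ground truth.

**Dispersers** walk with daily heading = bearing + N(0, s²) and
constant step `daily_speed`, with s = sqrt(2 log tortuosity): the
expected straightness ratio of such a walk equals the target
tortuosity exactly in the s → 0 limit and to first order otherwise
(E[cos δ] = exp(−s²/2) = 1/tortuosity), so a tortuosity-1 walk is
perfectly straight with CSLD ratio identically 1. The walk stops once
straight-line displacement reaches `target_distance`
(cumulative ≈ target × tortuosity; the red-like default 133.9 km ×
1.50 reproduces a ~200.8 km cumulative mean, verified unbiased within
2 SE over 20 replicates), then either settles (localized fixes on
land; an ice-borne endpoint is stepped ashore first — a stylized
"came ashore" jump after the dispersal proper has ended) or the track
truncates at death. Ice dispersals must start inside the ice window.

**Mortality** is exponential from November 1 with tactic-specific
daily hazard (default resident 5e-4, disperser/resident ratio 9). The
tactic's hazard applies across the whole winter at risk, which is
exactly the generative model a fixed-covariate Cox fit estimates — the
acceptance test fits an external Cox model to the exported table and
checks its 95% CI covers the planted ratio.

**What a green test does not establish.** The generator emulates the
statistical structure the pipeline measures — daily fixes, seasonal
range scaling, planted bouts and dispersals, tactic-dependent hazard —
and nothing else: no den attendance, no energetics, no Argos-style
location error, no heterogeneous duty cycles, no landscape resistance.
Passing tests certify the estimators against that stated world, not
against the idiosyncrasies of real collars; published range means from
field data used hand-tuned per-animal a values, so numeric equality
with them is expressly not expected (our summaries are shaped like,
not matched to, those tables).

## Degenerate inputs, tie-breaks, tolerances

* Collinear point sets abort hull construction with a named error;
  isolated points yield retained zero-area hulls.
* Boundary points count as inside (habitat: land wins on the
  coastline; coverage: on-hull fixes are covered).
* Point-in-hull tests use a 1e-9 scale-relative tolerance; slab
  boundaries below 1e-12 width are skipped.
* All-equal distance series give MAD 0 and bound = median (nothing
  exceeds); transforms undefined at 0 fall back to identity.
* Zero-variance-everywhere permutation tests report an undefined
  statistic (NA) rather than a fabricated p.
* Cohort tactic accuracy is evaluated with mortality disabled: a
  disperser killed before its departure leaves no evidence in the
  track, which is a property of the world, not of the classifier.

## Reproducibility

Every random stage takes a seed; per-animal streams are derived by
hashing the animal id with the master seed (always below 2³¹).
`run_pipeline()` writes a manifest (seed, config, package version,
file list) and rerunning any config is byte-identical, which the
acceptance suite asserts file by file.
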