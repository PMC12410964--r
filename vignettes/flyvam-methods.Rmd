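---
title: "flyVAM: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{flyVAM: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flyVAM)
```

# The measurement problem

Video activity monitoring of single flies replaces the classical
infrared-beam activity monitor with a camera above an arena of small
rectangular chambers, a pose-estimation network that reports one (x, y,
likelihood) triple per frame per fly, and analysis code that turns those
trajectories into behavioural metrics. flyVAM implements the analysis
side: it ingests the single-animal pose-table CSV dialect (three header
rows: scorer, bodyparts, coords; one bodypart; columns x, y, likelihood),
cleans rare misdetections, and computes circadian locomotor and
positional statistics, together with a ground-truthed trajectory
simulator so the entire pipeline can be validated without a camera, an
arena, or a trained network.

Two chamber formats recur throughout: a locomotion chamber of
23 mm × 15 mm with food along one short wall, and a two-choice
food-preference chamber of 50 mm × 10 mm with a food patch at each
extremity of the long axis. Recordings run at 5 frames per second — low
enough to keep multi-day videos tractable, high enough to resolve walking
bouts. All coordinates follow the image convention: 0-based pixels,
origin top-left, y increasing downward, every interval half-open
`[min, max)`.

# Misdetection control

Pose estimation occasionally reports a fly outside its chamber. Cleaning
is a three-step procedure:

1. **Chamber limits.** If the user supplies no geometry, the chamber
   rectangle is inferred from the detections themselves: per axis the
   `[0.001, 0.999]` quantile interval of confident detections
   (likelihood ≥ 0.9 by default), padded outward by 2 px. Quantiles
   rather than extrema make the estimate robust to the thin tail of
   confidently-reported strays; grossly wrong detections almost always
   carry low likelihood and are excluded before the quantile is taken.
   Inference refuses to run on fewer than 100 confident detections or
   when the inferred extent collapses below 5 px; a user-supplied
   geometry always overrides inference.
2. **Flagging.** A frame is flagged when its position lies outside the
   chamber, its likelihood is below the floor, or the position is
   missing. The likelihood floor (default 0.9, 0 disables) is this
   package's addition to the purely spatial rule: low-confidence points
   inside the chamber are jitter, and treating them like out-of-chamber
   detections keeps the distance statistic from accumulating noise.
3. **Interpolation.** Every flagged frame receives the coordinate-wise
   midpoint of the nearest preceding and nearest following unflagged
   detections. A run of consecutive flagged frames therefore receives a
   single constant position and contributes exactly zero distance
   internally. We read "the average position between the preceding and
   next detections" literally rather than as time-weighted
   interpolation: the midpoint is conservative, in that it never invents
   motion during an unobserved interval. Time-weighted linear
   interpolation is available as `method = "linear"` for users who
   prefer continuity over conservatism. Leading and trailing runs copy
   the nearest unflagged position (constant extrapolation).

Cleaning is idempotent, never touches unflagged positions, and
guarantees 100% containment afterwards.

# Activity metrics

**Distance.** Frame-to-frame Euclidean distances are summed into bins of
1, 10, 30 or 60 min. The interval between records *i* and *i+1* is
assigned to the bin containing record *i*'s timestamp; the incomplete
trailing bin is dropped. This assignment conserves total distance over
complete bins exactly — the property the test suite asserts to machine
precision. Distances are reported in pixels; multiply by the configured
mm-per-pixel scale when physical units are needed. Bins are anchored at
the recording start; the average-day fold re-anchors at ZT0.

**Virtual beam.** The beam-crossing statistic of the classical activity
monitor is emulated by a virtual line across the chamber midline
(midpoint of the long axis by default). A crossing is recorded when the
*held side* of the midline changes between consecutive records. The held
side uses hysteresis: a position exactly on the midline keeps the
previously held side, so a fly that stops on the line and retreats
registers nothing, and a touch-then-cross registers exactly once. A
standalone side query resolves the tie to the low side. Counting
detections *near* the midline (a band occupancy reading) is provided
separately as `midlineBandDetections()` for comparison, but crossings
are the primary statistic.

**Sleep.** The operational definition inherited from the beam-monitor
literature: every maximal interval of at least 5 consecutive minutes
without a beam crossing, bounded by the recording span edges, is one
sleep bout covering that interval. Sleep per time bin is the overlap of
bouts with the bin, in minutes, hence never exceeds the bin width. The
threshold is a parameter (`thresholdS = 300`). The same rule can be
applied to a movement-below-threshold event train by passing any
`CrossingEvents` object; the package applies it to virtual-beam events
by default because that is the definition's native habitat.

**Average day.** A binned series is folded onto one 24 h Zeitgeber
cycle: the value at ZT slot *h* is the mean over the requested number of
complete days of that fly's values at slot *h* (default 2 days, 60 min
bins). The fold requires the bin grid to align with ZT0 and refuses to
run with fewer complete days than requested.

**Group comparisons.** Day/night totals per fly (sums over complete 12 h
phases) are compared between groups with a two-sided Welch t-test; the
unequal-variance form is the default because nothing guarantees equal
spread between e.g. virgin and mated cohorts, and it reduces to the
Student form as variances equalise (a `varEqual` switch restores the
classical test). Hour-by-hour comparisons of average-day profiles use
two-sided Mann-Whitney tests, one per ZT hour, with multiplicity handled
as a false-discovery-rate question: Benjamini-Hochberg at q = 0.05 by
default, the two-stage Benjamini-Krieger-Yekutieli procedure as an
option. The discovery table records which group's median is higher at
each discovered hour. Dead-fly exclusion (zero crossings and under 1 px
of movement in the final 24 h) is available via `flagDeadFly()` but
never automatic.

# Positional analyses

Positions are first averaged within each second, then within each time
bin; seconds without frames inherit the previous second's value so
traces stay on a uniform grid. Per-second averaging contracts path
length, which the tests assert as an invariant. Occupancy heatmaps count
cleaned positions in equal-width half-open cells (default ≈ 1 mm cells
when the scale is known) and normalise to 1. The food-preference
histogram divides the chamber long axis into 10 equal bins (≈ 5 mm in
the two-choice chamber) and reports per-fly occupancy fractions; bins
are continuous equal-width intervals, which makes the heatmap's
long-axis marginal identical to the histogram when the grids align.
"The bin closest to a food" is the single bin containing the food
region's inner edge — the bin abutting the food wall. Occupancy at those
bins is compared between groups with per-fly Welch t-tests (per-fly
fractions, not pooled frames, so the test's unit of replication is the
fly). Interpolated frames count at their interpolated position, matching
the pipeline order; a flag excludes them.

# The synthetic fly

The simulator exists to make every stage testable against ground truth.
It is a two-state Markov walker, deliberately the simplest generator
that reproduces the qualitative structure of real recordings, with no
claim of biological realism:

* **Rest / move.** In rest the position is fixed. The per-frame
  probability of starting a move bout is
  `r(t) = base(phase) × startle(t) × siesta(t)`; a move bout ends with
  probability `moveExitRate` per frame (default 0.2, i.e. mean bout
  1 s at 5 fps).
* **Circadian modulation.** `dayRate` applies during (subjective) day,
  `nightRate` during night. Defaults (0.02 / 0.01 per frame) give a
  diurnal walker; experiments override them per group.
* **Startle.** After each transition between a light and a dark phase
  the entry rate is multiplied by `startleBoost` (default 6) for
  `startleDurationS` (default 300 s), emulating the lights-on and
  lights-off activity peaks. Subjective transitions under constant
  darkness do not startle.
* **Siesta.** Between ZT4 and ZT8 the entry rate is multiplied by
  `siestaDepth` (default 0.5), emulating the midday trough of virgin
  females; depth 1 disables it.
* **Movement.** While moving, step length is half-normal
  (`stepScale`, default 3 px/frame), heading diffuses with
  `turnSd = 0.6` rad, and with probability `foodBias` per frame the
  heading is redrawn toward the centre of the configured food region.
  Walls reflect.
* **Misdetections.** With probability `misdetectRate` (default 0.005)
  per frame the *reported* position is replaced by a point in a 20 px
  band outside a uniformly chosen wall with likelihood drawn from
  U(0, 0.5); clean frames report likelihood U(0.95, 1). The ground
  truth records true positions, the rest/move state sequence and the
  misdetection mask.

Determinism: a fixed seed reproduces a fly bit for bit. In grouped
experiments fly *i* (global index) uses
`seed_i = (master × 1000 + i) mod 2147483647`, so one integer reproduces
a whole cohort, and group overrides (any constructor argument) change
parameters without re-deriving seeds.

What the simulator does *not* emulate — inter-fly behavioural
correlation, grooming and micro-movements below the step scale,
egg-laying and feeding events, tracking error that stays inside the
chamber, lens distortion — bounds what passing tests show: they validate
the *analysis*, i.e. that known generative parameters are recovered
through cleaning, binning and testing, not that any biological claim
about real flies is true.

# Validation scale and numerical choices

The validation suite runs cohorts at the study's natural sizes — 16
flies for locomotion analyses, 12 per group for preference — over 3
simulated days at 5 fps for the circadian checks, and uses shorter
(1–2 h) recordings for the replicated power/null studies of the
preference test (100 biased and 200 null replicate experiments) where
occupancy fractions stabilise within the first hour. The
rank-test FDR study uses 500 null and 200 shifted synthetic hourly
matrices. Headline checks: the recovered night/day distance ratio of a
nocturnal walker (true ratio 2) must fall within 20%; startle peaks must
land within one 10-min bin of each light transition; a constant-rate
walker under constant darkness must produce an average-day profile flat
within 3 SE at every hour; the yeast-bin occupancy test must reject in
≥ 99% of biased replicates and in ≤ 10% of null replicates; mean false
discoveries across 24 hourly tests under the global null must stay below
0.05 × 24.

Numerical conventions worth stating: all spatial intervals are half-open,
so a chamber's maximum edge is outside it and bin/cell indices are
unambiguous; remainder pixels in the crop grid go to the lowest-index
rows and columns deterministically; midline ties resolve by hysteresis
in sequence and to the low side standalone; quantile-based chamber
inference uses R's default (type 7) quantiles; the trailing incomplete
bin is always dropped rather than padded; CSV floats are written with 12
significant digits, so round-trips are exact to 1e-9 relative; and the
walker's reflection clamps positions strictly below the upper wall so
containment is exact under the half-open convention.

# Known limitations

* Single animal per chamber; the multi-animal tracking dialect and
  identity swaps are out of scope.
* No smoothing beyond misdetection interpolation — no Kalman or spline
  filtering — and no rhythmicity statistics (periodograms); the binned
  series are exported tidily precisely so such analyses can be done
  downstream.
* The preference test treats the fly as the unit of replication and
  assumes flies are independent; arena-level effects are not modelled.
* Sleep is an operational proxy: a fly sitting on food for five minutes
  counts as asleep by the beam definition even while feeding or laying
  eggs. The positional analyses exist largely to expose exactly that
  ambiguity, and the package deliberately reports both.
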