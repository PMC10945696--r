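---
title: "Quantifying fly behavior in the four-quadrant optogenetic arena"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying fly behavior in the four-quadrant optogenetic arena}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flyarena)
library(dplyr)
```

## The assay

A group of roughly 20 walking flies is confined to a circular arena
(10 cm diameter, a few mm high) with a suction hole at the center. Air —
optionally odorized, delivered from the four corners — is drawn out
through that hole, so at any point in the arena the local upwind
direction is radially outward. Red LED panels can illuminate the whole
arena or two diagonally opposite quadrants, optogenetically activating
neurons in flies that express a red-shifted channelrhodopsin. Videography
at 30 frames/s feeds a tracker that emits per-frame positions (and
usually body orientations) per fly; that tracker table is where this
package starts.

Three stimulus protocols are modeled as labeled epoch schedules
(`build_schedule()`):

* **Conditioning** (`conditioning_v1`): three training cycles — 60 s of
  odor A paired with 30 one-second LED pulses spaced by 1 s dark, then
  60 s of odor B unlit — with a 60 s two-odor preference test after the
  first cycle and again after the third. Each biological replicate is a
  *reciprocal* pair of runs with the odor-reinforcement assignment
  swapped, which cancels innate odor bias.
* **Repeated activation** (`activation_v1`): six cycles of 10 s LED
  illumination spaced by 100 s dark, airflow but no odor. All kinematic
  screen parameters are epoch-locked to these pulses.
* **Lit-quadrant preference** (`light_preference_v1`): two 30 s tests
  with two diagonal quadrants lit, separated by a 150 s recovery, the lit
  pair swapped between tests.

Epochs are half-open `[t_start, t_end)` and frame *n* covers
`[n/fps, (n+1)/fps)`, so no frame is ever counted in two adjacent
windows.

## Per-frame kinematics

`track_kinematics()` computes, per fly and frame:

* **speed** — Euclidean centroid displacement between consecutive frames
  times fps (mm/s);
* **angular change** — `|wrap(θ_t − θ_{t−1})|`, wrapped to (−π, π], in
  radians/frame;
* **cos(upwind)** — the cosine of the angle between the heading and the
  outward radial direction `(p − c)/|p − c|`; +1 means facing dead
  upwind (away from the center), −1 dead downwind. Undefined within
  0.5 mm of the suction hole;
* **distance from center** — `|p − c|` in mm;
* **cumulative turning** — the trailing sum of angular change over five
  inter-frame changes (~167 ms at 30 fps). We read the published
  "five movie frames (150 ms)" description as a rounded account of the
  same five-change window; the window length is a parameter
  (`window_frames`). Turning is unsigned by default, matching the
  angular-change metric; `signed_turning = TRUE` gives net rotation
  instead.

Heading comes from the tracker's body orientation when present,
otherwise from the frame-to-frame displacement direction, held at its
previous value when the displacement is below `min_step` (default
0.1 mm) so that stationary jitter does not scramble it. Speed uses
centroid displacement (the tracker does not tell us more). Tracking
gaps are preserved as gaps: every differenced metric is `NA` at a gap
and the turning window is `NA` wherever it would span one —
interpolation would invent data.

## Epoch-locked summaries

For each activation pulse, the **ON** window is the first 2 s of the
10 s stimulus and the **OFF** window the 2 s immediately after the
stimulus ends; `summarize_on_off()` pools means over flies, frames, and
the six trials. `delta_distance_from_center()` is the mean distance from
center over the ON period minus the distance at stimulus onset (the full
10 s window by default; the first-2 s variant is behind a flag, since
the published definition does not state the averaging window).
`cumulative_turning_onset()` averages the turning window over the first
2 s of each pulse.

**Return probability** (`detect_return()`, `return_probability()`): the
origin is the position the fly occupied at the end of the LED stimulus,
and within the following 15 s the fly must first move ≥ 10 mm away and
then come back within 3 mm of the origin. Both events must fall inside
the 15 s horizon, with the excursion strictly before the return; this
offset-anchored reading is the only one consistent with scoring "the
position occupied at the end of the stimulus". Because the event needs
15 s of continuity, fly-trials tracked for less than 90% of the horizon
(configurable) are excluded from the denominator and counted. Detection
is monotone in its thresholds, which the test suite checks against a
brute-force scan of all frame pairs.

**Screen z-scores** (`zscore_screen()`): line-level parameter means are
standardized per parameter across all screened lines, control included,
with the sample (n−1) standard deviation. The published definition
"(values − mean)/standard deviation" does not name the reference
population; standardizing across lines is what reproduces a comparable
screen heat map, and it makes each column exactly mean 0, sd 1.

## Preference indices

`assign_quadrant()` classifies each frame into one of four angular
sectors; frames within 0.5 mm of a sector boundary (including near the
center, where all boundaries meet) keep the fly's previous quadrant —
a hysteresis rule that stops boundary jitter from flickering counts.
The per-frame preference index is

$$\mathrm{PI}_t = \frac{N_{\text{paired},t} - N_{\text{unpaired},t}}{N_{\text{tracked},t}}$$

with `N_tracked` the flies actually tracked in that frame (the
alternative — all loaded flies — silently deflates the index whenever a
fly is lost). The **memory score** is the frame-wise PI averaged over the
last 30 s of the 60 s test (an interval measure, not an endpoint count),
then averaged over the two reciprocal runs, unweighted. The
**light preference index** applies the same machinery with lit/unlit
labels over the last 5 s of each 30 s light test, averaged over the two
tests. Screening keeps lines whose absolute mean memory score exceeds
0.1 strictly; boundary cases are vanishingly rare in continuous scores.

## Rank statistics

The screen's line-versus-control statistics are implemented from first
principles in `kruskal_wallis()` and `dunn_vs_control()`:

$$H = \frac{\tfrac{12}{N(N+1)} \sum_i n_i\,(\bar R_i - \tfrac{N+1}{2})^2}
          {1 - \sum(t^3 - t)/(N^3 - N)},\qquad
z_i = \frac{\bar R_i - \bar R_c}
  {\sqrt{\bigl(\tfrac{N(N+1)}{12} - \tfrac{\sum(t^3-t)}{12(N-1)}\bigr)
   \bigl(\tfrac{1}{n_i} + \tfrac{1}{n_c}\bigr)}}$$

with pooled mid-ranks, ties corrected by the usual `t³ − t` terms, H
referred to a χ² with k−1 df and z to the standard normal, two-sided.
Comparisons are many-to-one against the designated control line, never
all-pairs. The Dunn adjustment is Bonferroni by default (the commercial
package historically used for this analysis applies a Bonferroni-family
correction; the method is a parameter, and unadjusted p-values are
always reported alongside). When every pooled value is identical the tie
correction degenerates and the test reports H = 0, p = 1 explicitly.
Both tests are reported unconditionally — the post test is not gated on
the omnibus test passing. The statistical unit for memory scores is one
reciprocal experiment (a movie pair), matching how the assay counts N.

```{r stats-example}
kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
tidy(dunn_vs_control(list(ctrl = c(1, 2, 3), test = c(4, 5, 6)),
                     control = "ctrl"))
```

## The synthetic cohort generator

`simulate_cohort()` exists so that every stage above is testable without
experimental recordings. Each fly is a discrete-time correlated random
walk: heading gains wrapped-normal noise with variance
`1/turn_concentration` per frame, per-frame speed is
`max(0, Normal(base_speed, speed_sd))`, and the walk reflects specularly
off the arena wall. Stimulus coupling mirrors the four phenotype
channels the screen measures, each independently switchable:

* `led_speed_multiplier` scales speed while the LED is on (speed
  channel);
* `onset_turn_boost` inflates heading-noise sd during the first 2 s of
  each pulse (onset-turning channel);
* `offset_upwind_bias` pulls the heading a fixed fraction of the way
  toward the outward radial direction per frame for 2 s after offset
  (upwind channel);
* `quadrant_bias` makes quadrant boundaries semi-permeable: a step that
  would leave a favored quadrant is rejected with probability *q* and
  the fly reflects off the boundary line, giving a stationary density
  ratio of about 1/(1−q) toward the favored label (preference channel).
  A simple reject-and-retry gate does *not* work here — a blocked fly
  retries the very next frame and passes after ~1/(1−q) frames, which
  is negligible against multi-second quadrant residence; the reflecting
  membrane is what actually produces a multiplicative dwell bias.

Defaults are the assay's standard conditions: 20 flies, 30 fps, 50 mm
radius, 10 ± 3 mm/s walking speed (ordinary walking pace for starved
flies in these arenas), heading-noise sd ≈ 0.35 rad/frame, all effect
channels neutral, no dropout. Per-fly seeds derive from the cohort seed
by a fixed multiplicative mixing chain mod 2³¹−1, so cohorts are exactly
reproducible and flies independent. Dropout removes frames entirely
(gaps, not NA rows), exercising the gap-handling paths.

What the generator does **not** emulate: odor plume structure, fly–fly
interactions, wall-following, body posture, and identity swaps. Passing
tests therefore certify the *analysis* — window bookkeeping, event
logic, estimator contracts, statistical calibration — not that real
flies behave like correlated random walks.

```{r sim-example}
sched <- build_schedule("activation_v1")
cohort <- simulate_cohort(
  sim_config(n_flies = 6, duration_s = 125, seed = 7,
             led_speed_multiplier = 0.5), sched)
km <- track_kinematics(cohort)
summarize_on_off(km, sched)
```

## Numerical choices and limitations

* Angles wrap to (−π, π]; quadrant sectors are computed from
  `atan2` with the configured `quadrant_phase` (the hardware does not
  fix the boundary orientation relative to the odor inlets, so it is a
  calibration parameter, default 0).
* The onset frame of a pulse is the frame whose interval contains the
  onset time; the return origin is likewise the frame containing the
  offset time.
* Problem sizes in the shipped tests — 500 oracle tracks, 1000
  null replicates for test size, 200 seeded cohorts for the null memory
  score, 8 replicates per simulated genotype — were chosen as the
  smallest ensembles at which the Monte-Carlo bands in question are
  meaningfully narrow.
* Per-epoch tracklet identity is sufficient for every metric except
  return detection, which needs 15 s of continuity after offset;
  insufficiently covered fly-trials are excluded and counted rather
  than stitched.
* The package consumes tracker output; it does not detect, segment, or
  track flies, and it deliberately performs no trajectory smoothing
  beyond the heading hold rule.
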