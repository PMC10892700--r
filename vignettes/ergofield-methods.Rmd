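---
title: "Continuous ergonomic risk scores and in-shoe plantar pressure kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Continuous ergonomic risk scores and in-shoe plantar pressure kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ergofield)
```

## What ergofield models

Occupational field studies of work-related musculoskeletal disorder (WRMSD)
risk increasingly replace pen-and-paper posture observation with wearable
sensors: inertial measurement units stream joint angles throughout a work
shift, and in-shoe pressure insoles record the vertical load on the feet.
`ergofield` implements the analysis layer for such a study design:

* per-frame **RULA** (Rapid Upper Limb Assessment) scoring of joint-angle
  streams, summarised as the working-time distribution over the four action
  levels and a continuous whole-process final score;
* per-frame **CUELA-style** zone categorisation (green / yellow / red joint
  angle ranges) with a distribution-weighted final score on a 1-3 scale;
* six-region **plantar pressure kinetics** - mean pressure, peak pressure,
  pressure-time impulse, loaded-time fraction and loaded-sensor percentage -
  per foot side and measurement time;
* **Borg CR-10 body-map** composites (total, upper extremity, core, lower
  extremity) and a fatigue visual analog scale;
* a **repeated-measures inferential layer**: Shapiro-Wilk screening,
  one- and two-factor within-subject ANOVA with Greenhouse-Geisser
  correction and partial eta squared, and Bonferroni-adjusted paired post
  hocs with confidence intervals;
* a **seeded synthetic work-shift generator** so that every stage of the
  pipeline is testable end to end without access to raw recordings.

The emulated design is a pre/post comparison: each worker is captured once
at the start of an afternoon shift and once after three hours of
uninterrupted work, with surveys after each capture. Production workers
additionally wear pressure insoles in standardised safety shoes.

## RULA scoring

RULA is a worksheet instrument: joint angles are binned into partial scores
(upper arm 1-4, lower arm 1-2, wrist 1-3, wrist twist 1-2, neck 1-4, trunk
1-4, legs 1-2, plus posture modifiers), combined through three lookup tables
(A: arm/wrist; B: neck/trunk/legs; C: grand score 1-7), with muscle-use and
force/load modifiers added to the A and B scores before the final lookup.
The lookup tables ship as an editable plain-text file
(`inst/extdata/rula_tables.csv`) and are validated on load; the angle bins
are encoded in `R/rula.R` with boundary values always assigned to the lower
(safer) score.

Decisions that the worksheet leaves open for continuous data, and how this
package resolves them:

* **Neutral bands.** An exported angle is almost never exactly 0, so "neutral
  wrist" is `|flexion| <= 5` degrees and "upright trunk" `|flexion| <= 5`
  degrees; neck extension needs to exceed 5 degrees before the extension
  score (4) applies. Abduction beyond 45 degrees marks the upper arm
  "abducted"; wrist deviation beyond 10 degrees marks it "bent from the
  midline"; wrist twist beyond 45 degrees counts as near end-of-range.
* **Static muscle use.** The worksheet's "posture held longer than one
  minute" becomes `detect_static()`: a frame is static when the trailing 60 s
  of the contributing angle trace spans less than 10 degrees. Repetition
  (at least 4 cycles/min) is accepted as a flag rather than detected,
  because a robust cycle counter would need task knowledge the data model
  does not carry.
* **Bilateral combination.** Left and right limbs are scored separately and
  each frame takes the worse (higher) grand score. The mean and
  side-specific traces remain available in the per-frame output.
* **Final score.** The working-time distribution over the four action levels
  (grand 1-2, 3-4, 5-6, 7) is the primary descriptive output. The final
  score that condenses it is the time-weighted mean of per-frame grand
  scores: it is continuous (cohort means need not be integers) and preserves
  the dynamics of the whole process. A modal and a 90th-percentile variant
  are available through `final_rula_score(method =)` for users who prefer a
  worst-dominated summary.

## CUELA-style zone scoring

Each continuous channel is assigned a green (acceptable) interval nested in
a yellow (limited acceptable) interval; anything outside is red. The frame
zone is the worst channel zone, and the final score is the zone-weighted
time distribution `1*p_green + 2*p_yellow + 3*p_red`, which places it on a
1-3 scale directly comparable to a 1-7 RULA mean. Two conventions:
boundaries are closed on the greener side (an angle exactly on a green/yellow
boundary is green - deterministic and benefit-of-the-doubt), and the
threshold table is a plain-text file (`inst/extdata/cuela_thresholds.csv`)
because the official instrument's angle ranges are not published in
machine-readable form; the shipped defaults are conventional ergonomic
ranges (e.g. trunk flexion green up to 20 degrees, yellow to 60; neck green
to 25, yellow to 45) and every deployment can substitute its own table.

## Plantar pressure kinetics

Recordings are zero-calibrated against an unloaded sitting baseline
(per-sensor baseline mean subtracted, negatives clamped), and the 3-5 most
posterior-lateral sensors are excluded depending on shoe size (EU 39: 3,
41/43: 4, 45: 5) because the safety-shoe heel guidance loads them
artefactually. Sensors live in normalized foot coordinates - length 0% at
the posterior heel, width 0% at the medial edge - and are segmented into six
regions: rearfoot (0-30% length), midfoot (30-60%], metatarsal heads
(60-80%], forefoot (80-100%], and independently inner foot (0-60% width)
and outer foot (60-100%]. Printed integer bounds like "31-60%" are resolved
as contiguous upper-closed real intervals so no sensor can fall into a dead
band; a sensor at exactly 30% length is rearfoot.

Per-sensor statistics are averaged over a region's member sensors (never
pooled across frames first), which removes recording-length effects from
between-region comparisons:

* mean pressure: each sensor's time-mean over its *loaded* frames (at or
  above 0.6 N/cm^2, the device's lower measurement bound - the package's
  definition of "loaded", since no published threshold exists). A sensor
  never loaded contributes 0. `mean_over = "all"` switches to whole-recording
  denominators, since the study description is ambiguous on this point.
* peak pressure: mean of per-sensor maxima (not the single highest value in
  the region, which one outlying sensor would dominate).
* impulse: per-sensor integral of pressure over time (Ns/cm^2), additive
  over time windows and linear in pressure - it emphasises sustained
  moderate loading where peak pressure emphasises transients.
* loaded-time fraction and loaded-sensor percentage: a sensor counts as
  loaded for the percentage summary when it is loaded in at least 1% of
  frames; a single-frame criterion would be noise-fragile and no persistence
  rule is published.

## Statistics

The design is fully within-subject (phase, side), so the ANOVA uses the
classical balanced sums-of-squares decomposition with each effect tested
against its own effect-by-subject interaction. Greenhouse-Geisser epsilon is
estimated from the covariance of orthonormally contrasted condition scores;
for two-level factors it is exactly 1 and F equals the squared paired t
statistic, which the tests assert analytically. Partial eta squared is
`SS_effect / (SS_effect + SS_error)`. Incomplete designs are refused rather
than imputed; no outliers are excluded anywhere; non-normality flagged by
`shapiro_screen()` does not abort the ANOVA (the rmANOVA is robust to
normality violation alone) but is attached to the report for the reader.
Post hocs are paired t contrasts with Bonferroni adjustment: p multiplied by
the number of pairs (capped at 1) and CIs widened to the `1 - alpha/m`
level. The two-factor model reports the phase-by-side interaction but flags
it informational, since the emulated design reports main effects.

## The synthetic generator

`simulate_cohort()` emulates the data-generating situation of the field
study, with every assumption a `cohort_spec()` field:

* **Surveys.** Exertion and fatigue are truncated normals on the 0-10 scale
  with within-subject phase correlation 0.6 and programmed shifts
  (defaults d = 0.78 for exertion, 0.65 for fatigue, matching the emulated
  design's pre/post effect sizes). Body-map region ratings scatter around
  the worker's exertion level with small group offsets (upper extremities
  loaded slightly above, lower extremities below - upper-body-oriented
  work).
* **Gait pressure.** Per step, a Gaussian pressure blob translates heel to
  toe over the stance phase (60% of the cycle, 50 steps/min per foot) under
  a double-hump amplitude envelope (heel strike, push-off) multiplied by a
  foot-length load profile that unloads the arch, so rearfoot loading
  dominates and the midfoot carries least - the ordering visible in
  rearfoot-dominant occupational loading. Amplitudes are linear in
  `peak_scale` up to the 64 N/cm^2 device ceiling, and per-step noise is
  multiplicative, so doubling the scale doubles every impulse - a property
  the tests exploit. The right foot's amplitude is the left's times the
  programmed asymmetry ratio (default 1.15, the right-dominant cohort), and
  by default nothing changes between phases (`pressure_time_effect = 0`).
* **Angles.** Channel-wise sinusoidal work cycles plus Gaussian jitter
  around task-profile means (a dynamic production profile and a sedentary
  office profile), with boolean worksheet modifiers switching on blockwise.
* **Baselines.** Unloaded captures with per-sensor lace-binding offsets; the
  worn recordings include the same offsets, so zero calibration recovers the
  gait signal.

What the generator does *not* emulate - and what passing tests therefore do
not show about real data: sensor drift and hysteresis, shear forces, gait
spatiotemporal variation (the step grid is regular), posture-pressure
coupling (angles and insoles are drawn independently), and realistic
ergonomic score *levels* (the task profiles produce plausible but not
calibrated RULA/CUELA magnitudes; only their paired structure across phases
is meaningful). Recovery tests therefore check programmed effects -
detection of the exertion shift and the side asymmetry, a controlled
false-positive rate for the null time effect - not any particular field
cohort's statistics, which would require the underlying raw recordings.

## Numerical and scale choices

* Time windows are half-open `[start, end)`: adjacent windows partition
  frames exactly, making impulse additive across splits.
* Sample rates are inferred from the median inter-frame gap; gaps deviating
  more than 1% are rejected (the devices sample at fixed 60/100 Hz).
* Cohort-scale simulations in the tests and the reproduction script use
  shortened sessions (20-120 s instead of the full 12 min) at 25-50 Hz
  insole rates: the paired statistical structure being exercised does not
  depend on session length, and the choice keeps the full suite fast. The
  100-cohort recovery test runs 24 workers per cohort with 18 insole
  wearers - the emulated subject counts are never scaled.
* Report tables round to two decimals for display only; machine-readable
  outputs keep full precision.

## Limitations

The RULA angle bins, abduction/deviation thresholds and the CUELA ranges are
documented conventions, not vendor-certified reproductions; both instruments
warn that automated scoring of checkbox items (arm support, load handling)
requires configuration the angle stream cannot carry. CUELA parts 2 and 3
(moments and forces) are out of scope, as are shear forces, gait
spatiotemporal parameters and centre-of-pressure trajectories. The
whole-process final scores are summaries of per-frame worksheets; they are
comparable within a study that fixes these conventions, not across software
that chooses differently.
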