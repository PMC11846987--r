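---
title: "From raw accelerometry to genre-level kinematics: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From raw accelerometry to genre-level kinematics: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(esportkin)
```

`esportkin` turns raw tri-axial accelerometer recordings of a computer-mouse
user's right upper limb (hand, forearm, arm sensors, 500 Hz, milli-g) into
per-session kinematic metrics and cohort-level comparisons across game
genres (FPS, MOBA, Adventure). This vignette explains the processing model,
the parameters that matter, what the synthetic generator does and does not
emulate, and the design decisions taken where the method was genuinely
under-determined.

## The pre-processing chain

Each of the nine axis traces is processed independently, in a fixed order:

1. **Outlier replacement.** Samples further than `outlier_k` (default 3)
   standard deviations from the whole-session mean are replaced by linear
   interpolation between the nearest surviving neighbours; edge outliers
   take the nearest valid value. Mean and SD are computed once, over the
   full trace, with the population (divide-by-n) SD — the convention of the
   numeric stacks this kind of script is usually written in. The pass is
   deliberately single-shot: an iterated re-estimation would flag ever more
   of the signal's own ballistic peaks, and there is no principled stopping
   rule for it here. A constant trace has SD 0 and the strict `>` test then
   flags nothing. Note that on real, heavy-tailed movement data a 3-SD rule
   inevitably clips some genuine movement peaks (about 1–2% of samples);
   `fraction_unchanged` reports how much survived.
2. **Gravity zeroing.** The session mean is subtracted per axis. This
   assumes sensor orientation is constant over the session; no attitude
   tracking is attempted.
3. **Unit conversion.** mG to m/s² with standard gravity, 9.80665/1000.
4. **Band-pass filtering.** A Butterworth band-pass of design order
   `filter_order` (default 2) between `band_low_hz` = 0.5 Hz and
   `band_high_hz` = 11 Hz. By default the filter runs forward–backward
   (zero phase), because the analysis is offline and displacement metrics
   should not inherit a phase lag; `zero_phase = FALSE` gives the single
   causal pass. Forward–backward filtering is implemented with
   odd-reflection padding of three periods of the lowest corner frequency
   at each end, so that the 0.5 Hz start-up transient decays inside the
   padding rather than inside the data (naive zero-state filtering leaks
   roughly half the DC level into the edges; with padding the DC leakage is
   below 1e-6).
5. **Double integration.** Cumulative trapezoid integration, acceleration →
   velocity → displacement, starting at zero. With `drift_correction = TRUE`
   (default) each integral is re-high-passed at `band_low_hz` and
   mean-removed: double integration of broadband noise otherwise
   accumulates a random walk that dominates every displacement-derived
   metric within seconds. `drift_correction = FALSE` (the CLI's
   `--strict-paper`) gives the bare cumulative trapezoid.

Finally the per-frame **global magnitude** combines the three axes. The
default, `as_printed`, is the sum of absolute components |x|+|y|+|z|; the
`euclidean` option is the conventional vector norm. The sum-of-absolutes
form is retained as the default because it is what the session metrics are
defined on in the workflow this package reproduces, but it is worth knowing
that it exceeds the Euclidean norm by a factor of up to √3 (≈ 4/π on
average for isotropic signals), which propagates into RMS and distance
values.

## The metric suite

For each session the package reports:

- **RMS global acceleration** per segment (m/s²), and the distal-over-
  proximal **segment ratios** hand:forearm and forearm:arm. Ratios above 1
  mean the distal segment moves with more acceleration than its proximal
  neighbour (wrist-dominated mouse control).
- **Velocity zero-crossings** summed over the three hand-velocity axes, a
  repetitive-motion index. Exact zeros carry the previous sign forward so a
  touch-and-return is one crossing, not two. The `deadband` (m/s, default
  0) treats |v| below threshold as zero. The default is faithful to the
  original definition, but note a statistical fact: the zero-crossing rate
  of band-limited Gaussian noise is independent of its amplitude (~12 s⁻¹
  per axis in a 0.5–11 Hz band), so whenever the hand rests, raw counts are
  dominated by sensor noise. Where we report counts on synthetic cohorts we
  use a 2 mm/s deadband, roughly 6× the velocity noise floor of the
  generator's 2 mG sensor noise and far below ballistic peak velocities
  (~0.1–1 m/s).
- **Cumulative distance** (m): the sum of absolute frame-to-frame changes
  of the global displacement magnitude. The typeset definition of this
  quantity telescopes to a difference of endpoints; the implemented form is
  the self-consistent prose definition Σ|ΔD|.
- **95% coverage ellipse** of the hand's x–y displacement, in cm. The
  sample covariance of the displacement point cloud is eigen-decomposed and
  the semi-axes are √(q·λ₁) ≥ √(q·λ₂) with q the χ²(2) quantile at the
  coverage level (5.9915 at 0.95); area A = πab, shape the long:short ratio
  a/b (1 = circular footprint). This is a *population-coverage* ellipse of
  the displacement cloud — the object of interest is where the hand went,
  not the standard error of its mean position. The construction was a
  design decision; the source workflow names the ellipse but not its
  construction.

A motionless segment (zero RMS or a collinear displacement cloud) flags the
summary (`ellipse_degenerate`, `NA` ratios) instead of failing the session.

## Cohort statistics

The cohort layer mirrors a standard between-groups workflow: Shapiro–Wilk
per group and Levene's test (centre = mean, the SPSS convention) for
homogeneity; a natural-log transform with a percentile bootstrap CI of each
group's transformed mean (B = 1000, 95%, deterministic under the run seed);
a one-way ANOVA on the transformed values with η² = SS_between/SS_total;
Fisher LSD pairwise t tests on the pooled within-group mean square with the
omnibus residual df, unadjusted by definition; a genre × DPI Pearson χ²
with pairwise 2×2 follow-ups (each DPI level × each genre pair, nine
comparisons) against the Šidák threshold 1−(1−α)^(1/9) = 0.0057, with φ² as
the pairwise effect size; and a one-sample t of the long:short ratio
against 1 per genre, on the raw ratio scale because the reference value 1
is defined there.

Two choices deserve a note. The base of the log transform is immaterial to
F, p and η² (it shifts the transformed means additively), so natural log is
used. And the bootstrap is a *supplement* — it provides CIs on the
transformed group means; the F test itself is not bootstrapped. How exactly
a bootstrap "supplemented" the original SPSS workflow is not recoverable
from its description, so the package implements the defensible reading and
exposes both pieces separately. The percentile CI is known to undercover
slightly at small n (measured ≈ 93–94% at n = 30 for a nominal 95%); that
is a property of the percentile method, not a bug.

## The synthetic generator

`simulate_session()` exists so that every pipeline stage can be tested with
analytic ground truth and no data download. Its model:

- Ballistic events arrive as a Poisson stream (`event_rate_hz`); overlapping
  events are thinned so strokes never superpose.
- Each event is an **out-and-back minimum-jerk flick** from a home position:
  a fifth-order minimum-jerk stroke to a target, a 50–150 ms dwell, and a
  stroke back. Minimum-jerk is the standard ballistic-reach form, is
  band-limited compatibly with the 0.5–11 Hz analysis band, and obeys the
  15/8 peak-velocity factor used as a self-check. Re-centring is what real
  mouse users do on a bounded pad, and it makes path-length ground truth
  well defined: without it a 10-minute random walk of targets leaves any
  plausible mousepad.
- Targets are drawn from a genre-specific 2D Gaussian (`spatial_cov_cm2`),
  scaled so `amp_mean_cm` is the mean flick amplitude and multiplied by a
  unit-mean-square log-normal amplitude factor (CV `amp_sd_cm/amp_mean_cm`),
  which leaves the generative covariance exact for recovery tests. A small
  vertical residual (5% of amplitude) keeps the x–y ellipse well posed while
  reflecting essentially planar mouse motion.
- The hand acceleration is computed analytically, scaled by
  `segment_attenuation` for the forearm and arm (proximal segments move
  less), offset by a static `gravity_mg` vector, and corrupted by white
  noise (`noise_sd_mg`, default 2 mG, a realistic MEMS noise floor over
  this bandwidth) and rare spike artefacts (`outlier_rate`, amplitude 12×
  the clean-trace SD so they are unambiguous outliers).

The genre presets encode the qualitative regimes reported for the three
genres — FPS: largest, most anisotropic flicks (wide oblong footprint,
longest travel); MOBA: highest event rate in a compact near-circular area;
Adventure: sparsest and slowest strokes over an oblong area — with rates
and amplitudes chosen once so that 10-minute cumulative distances land near
the reported cohort scale (tens of metres). They are *not* calibrated to
reproduce the human cohort means: the generator has no skill model, no
in-game context, no DPI-dependent cursor gain, no left hand, no fatigue,
and (per session) no slow postural wander. Consequently synthetic group
contrasts are cleaner than human ones even with the between-participant
heterogeneity `simulate_cohort()` adds (log-normal scaling of amplitude and
event rate, CV 0.25), and the absolute displacement-ellipse areas are
smaller than in real data, where slow wander and residual drift spread the
point cloud. Passing recovery tests therefore demonstrates that the
pipeline measures what the generator planted — not that the generator
reproduces human gameplay.

## Ground truth, recovery, and the norms that enter them

Two recovery details are deliberate:

- **Path length** is validated under the `euclidean` norm: path length is a
  Euclidean quantity, and the out-and-back geometry makes the Euclidean
  global displacement trace rise and fall by exactly the stroke length. The
  default `as_printed` norm would add a known L1/L2 inflation of about 4/π.
  Median recovery error on FPS presets is a few percent (the residual bias
  is dominated by the outlier stage clipping the largest acceleration
  peaks).
- **Ellipse shape** is validated against √(λ₁/λ₂) of the generative target
  covariance. The sample axis-ratio estimator is upward-biased at small
  point counts, so shape recovery uses full-length (10-minute) sessions,
  where the bias is within the 10% budget.

## Numerical choices and degenerate inputs

- Filter warm-up: traces shorter than 3×(2·order+1) samples are rejected;
  corner frequencies must lie below Nyquist.
- Time stamps in recording CSVs are derived (index/rate); deviations beyond
  1 µs are rejected rather than resampled, because uniform spacing
  underlies the trapezoid integration.
- Zero-variance groups: Levene's boundary case (all deviations zero)
  reports p = 1; an all-identical ANOVA reports F = 0, η² = 0 rather than
  erroring; an identical LSD pair reports p = 1.
- All stochastic operations (bootstrap, simulation) restore the caller's
  RNG state and are bitwise reproducible under their seed; cohort runs
  derive per-participant and per-stream seeds from the single run seed.

## Problem sizes used by the test-suite

The suite validates distributional properties at sizes chosen to keep the
whole run at about a minute while leaving comfortable statistical margins:
noise-floor and attenuation checks on 60 s sessions; path-length recovery
on ten 120 s sessions; ellipse-shape recovery and the isotropic-field check
on full 600 s sessions (five and three seeds — the axis-ratio bias, not the
variance, is the binding constraint); bootstrap coverage over 1000
replicates of n = 30; and the type-I error of the log-ANOVA path over 2000
null cohorts of the study's 32/16/15 group sizes.

## Known limitations

Orientation is assumed constant (gravity removal by mean subtraction only);
metrics inherit the quirks of the printed magnitude definition unless the
Euclidean mode is selected; zero-crossing counts at deadband 0 are
noise-dominated during idle time; displacement metrics describe the
band-passed, drift-corrected signal, not absolute position; and the
synthetic cohort is a validation instrument, not a stand-in for human
inter-individual variability.
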