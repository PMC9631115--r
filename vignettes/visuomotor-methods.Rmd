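---
title: "Methods: behavior randomization, widefield processing, and unit QC"
author: "visuomotor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: behavior randomization, widefield processing, and unit QC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(visuomotor)
```

This package implements the bespoke computations of a head-fixed mouse
visuomotor learning experiment: a conditional-randomization test that asks
whether wheel movements are time-locked to visual stimuli, a widefield
calcium-imaging processing chain, and spike-sorted unit curation with a
shuffle test of responsiveness. Everything runs on synthetic data with
known ground truth, so each stage is testable without recordings. This
vignette explains the models, the tunable parameters, and the design
choices made where the procedures left latitude.

## The task and its replayable timer logic

A trial separates the previous outcome from the next stimulus by two
delays drawn uniformly on a 100 ms grid: a fixed inter-trial interval
(ITI, trained range 4–7 s) and a quiescence period (0.5–2 s) whose timer
restarts whenever the wheel moves. The stimulus therefore appears at an
unpredictable time, and only when the animal is still. After onset the
stimulus is yoked to the wheel: cumulative counterclockwise displacement
past the reward threshold ends the trial with reward; clockwise past the
punish threshold ends it with white noise.

`replay_stimulus_time()` reproduces this logic deterministically against a
fixed movement record: given the previous outcome time and a delay pair,
it returns exactly the onset the task program would have produced. The
session generator uses the *same* replay function, which gives the
package's central structural invariant: re-replaying each recorded trial's
delays against the finished wheel trace reproduces every recorded stimulus
onset bit-for-bit. Movement events are sample times where wheel speed
exceeds a detection floor; a movement landing exactly at timer completion
counts as a reset (ties break conservatively toward "no stimulus yet"),
applied identically in generation and replay.

Defaults chosen where the task description is silent: the wheel is sampled
at 1 kHz; movement bouts are boxcar velocity pulses (duration 0.2–0.4 s,
speed 300–600 deg/s, 85% counterclockwise); reward/punish thresholds are
±90 deg of cumulative displacement from onset; unanswered trials time out
10 s after the stimulus; a rewarded trial adds a 1 s consumption period
before the next ITI. Background bouts form a thinned Poisson process
(default 0.35 bouts/s, matching a mouse that turns frequently but
untimed); in the trained regime each answered stimulus adds a
counterclockwise bout at a latency drawn from a shifted log-normal whose
mode sits at 150 ms, the latency band trained animals reach.

## The conditional-randomization test

The scientific problem: a mouse that merely turns the wheel more often
shows shorter reaction times (stimulus onset to next movement) without any
sensorimotor association. The test conditions away the movement process:
keeping the wheel record and every observed post-stimulus movement time
fixed, it redraws each trial's delay pair uniformly on the grid, accepting
a draw only if replaying the timer logic yields a stimulus whose next
movement is exactly the observed one. Under the null hypothesis that
movements ignore stimuli, the observed delays are a uniform draw from this
acceptance set, so the observed median reaction time is exchangeable with
medians computed from accepted redraws.

Implementation choices:

- **Test statistic** — median across trials of reaction times, excluding
  values under 100 ms (`rt_floor`), which are attributed to coincidental
  timing. The same exclusion is applied to every null median.
- **Direction and p-value** — one-sided lower tail ("faster than
  chance"), `p = (1 + #{null medians <= observed}) / (1 + n_resamples)`.
  The add-one correction guarantees finite-sample validity; ties count
  toward the null tail. A two-sided option exists but is off by default.
- **Samplers** — the delay grid is finite (496 combinations at the
  trained ranges), so the default sampler enumerates each trial's
  acceptance set once (`exact_conditional_null()`) and resamples from it.
  A literal rejection sampler is provided and falls back to enumeration
  for any trial whose acceptance rate would exceed a 1000-proposals-per-
  draw budget; the two agree to within the two-sample concentration bound
  in the test suite. Default 10,000 resamples; trials whose stimulus was
  never followed by a movement are excluded from observed and null
  statistics alike.
- **Derived quantities** — `association_day()` is the first day with
  p below 0.05; the task performance index is
  (chance − observed)/(chance + observed) medians, positive when faster
  than chance; `split_thirds()` makes contiguous thirds of trials with
  the earlier groups taking the remainder.

**Calibration caveat.** Each trial's redraw conditions on the *observed*
previous-outcome time, which is itself a function of the previous trial's
delays. This per-trial approximation — inherent to the procedure as
described — leaves a small residual anticonservativeness when outcomes
couple consecutive trials: across seeds we measure type-I error of
roughly 0.04–0.065 at the 0.05 level over 500 null sessions of 60 trials,
whereas a variant cohort with delay-independent trial boundaries is
exactly calibrated (0.0475 in the same harness). The acceptance check
allows the binomial 95% upper edge at the simulated session count.

## Widefield processing chain

The imaging model: a camera acquires at 70 Hz with strictly alternating
blue (calcium-dependent) and violet (calcium-invariant) illumination,
giving 35 Hz per channel. Movies are compressed by truncated SVD
(`svd_compress()`); every temporal operation then acts on the small
`S V'` matrix, and by linearity equals the pixel-space result after
reconstruction (tested to floating-point tolerance). Production-scale
recordings retain 2000 components; the synthetic fixtures here use tens.

- **Hemodynamic correction** (`hemodynamic_correct()`): blood-volume
  artifacts enter both channels. The violet channel is sub-sample shifted
  onto blue frame times by linear interpolation (the simplest
  phase-accurate choice; the alignment method was otherwise unspecified);
  both channels are band-passed 5–15 Hz (zero-phase order-2 Butterworth)
  to emphasize the heartbeat band; a per-pixel scale is regressed by OLS
  without intercept on the filtered signals; and the *unfiltered* scaled
  violet is subtracted from blue — our reading of the stated order of
  operations, which preserves slow calcium signal exactly. Fitting runs
  on 3× spatially downsampled blocks (hemodynamic gain is spatially
  smooth), broadcast back to pixels. The correction never touches the
  violet channel and is idempotent to under 1% RMS.
- **dF/F** (`normalize_dff()`): linear detrend, 0.01 Hz zero-phase
  high-pass, then `(F − F0)/(F0 + c)` with `F0` the per-pixel session
  mean. "Softened by the median fluorescence across pixels" is
  interpreted as *additive* regularization, `c = median(F0)`, the reading
  that keeps dim pixels bounded without rescaling bright ones; this was a
  genuinely open choice and is configurable.
- **Deconvolution** (`deconvolve()`): frequency-domain division with
  Tikhonov regularization relative to the kernel's peak power
  (`lambda`, default 1e-3). The indicator kernel is consumed as an asset;
  `gcamp_kernel()` supplies a difference-of-exponentials stand-in with
  GCaMP6s-like 50 ms rise and 0.8 s decay, unit peak. `lambda` should
  scale with the noise-to-signal ratio: 1e-5 suffices for the near-
  noiseless fixtures, larger values for recordings.
- **Recasting** (`recast_to_master()`): `t(U_master) U_exp SV_exp`
  projects one recording's temporal components into a shared spatial
  basis; exact when the master contains the experiment's column space.
- **Alignment** (`align_days()`): vasculature edge maps (raw minus
  Gaussian-blurred mean image) are rigid-aligned to a reference day by an
  exhaustive rotation grid (±5° in 0.25° steps) with FFT cross-
  correlation translation and parabolic sub-pixel refinement; ties break
  toward the smallest displacement. Across-mouse affine alignment and
  atlas registration are out of scope (they require an external atlas
  asset).
- **Hemisphere subtraction** (`fit_hemisphere_ratio()`,
  `hemisphere_subtract()`): under the additive model
  `F_L = v_L V + m_L M`, `F_R = v_R V + m_R M` with unilateral visual and
  bilateral movement components, counterclockwise delay-period movements
  with no stimulus identify `m_L/m_R`. Epoch-triggered snippets are
  averaged within day, then across days, then a no-intercept scale is
  fitted. `F_L − (m_L/m_R) F_R` cancels the movement component exactly at
  the exact ratio, leaving `(v_L − m_L v_R/m_R) V`; positive values mean
  more left-hemisphere activity.
- **Field sign** (`field_sign_map()`): per bootstrap over square
  presentations (default 10, seeded), square-mean responses are Gaussian-
  smoothed, each pixel's response-weighted (rectified — raw-versus-
  thresholded weighting was unspecified) center of mass in azimuth and
  elevation is computed, and the sign is the sine of the angle between
  the elevation and azimuth gradients, averaged over bootstraps. With
  image coordinates row-major and origin top-left, azimuth advancing
  along columns and elevation along rows gives +1; mirror-image areas
  give −1; the sign is invariant to a global rotation of cortical
  coordinates.

The synthetic stack (`simulate_widefield()`) plants: a unilateral visual
component (posterior and anterior left-hemisphere fields, weak mirrored
gain 0.2 on the right), a bilateral movement component (left/right gain
ratio 0.8), a shared 10 Hz heartbeat artifact with slow amplitude
modulation and smooth pixel gains (inside the 5–15 Hz correction band by
construction), and white noise. What it does not emulate: photon shot
noise statistics, optics and scattering, vascular occlusion geometry,
slow photobleaching, or behavior-correlated hemodynamics — so passing
recovery tests demonstrate correctness of the algorithms under the
additive model, not robustness to every property of real recordings.

## Electrophysiology

`classify_unit_quality()` applies seven criteria: somatic waveform shape
(one trough preceding and exceeding at most two peaks, counted with a
prominence threshold of 10% of the trough amplitude — the criterion needs
a threshold the description omits); spatial amplitude-decay slope above
−20 (the printed number is unitless; we express it per channel spacing
and make the floor configurable); trough-to-peak duration within
100–800 µs; baseline amplitude under 30% of maximum (baseline = first 20%
of the waveform window); estimated missing-spike fraction under 20%
(maximum-likelihood Gaussian fit to the amplitude distribution truncated
at the detection floor — the binning-free fit replaces an unspecified
histogram procedure); at least 300 spikes; and refractory contamination
`F_p` under 10%, solving
`r = 2 (tau_R − tau_C) N^2 (1 − F_p) F_p / T` for the smaller root, with
`tau_R` = 2 ms, `tau_C` = 0.1 ms, and `F_p = 1` flagged when the
discriminant is negative. Violations are counted over all spike pairs
with inter-spike interval in `(tau_C, tau_R]`; consecutive-pair counting
is available as an option.

One bias is worth stating plainly: the quadratic above accounts only for
contaminant-versus-neuron violation pairs. A temporally uniform
contaminant also collides with itself, contributing an expected share
`F_p / (2 (1 − F_p))` of the count, so inverting the formula
overestimates — by about +0.006 at a true fraction of 0.10, +0.017 at
0.15, and +0.035 at 0.20 (verified against decomposed pair counts in the
test suite). Near the 10% acceptance threshold the estimator is accurate
to well under two points; at 0.20 it is not, and the recovery test at
that level records the fact rather than hiding it.

`shuffle_responsiveness()` compares mean firing in a baseline window
(−500:−300 ms before events) against a response window (0:200 ms after
stimuli; −100:+100 ms around movements): the null swaps the two values
within each trial with probability ½, 1000 times; the p-value is
two-sided (both positive and negative responders are reported) with the
add-one correction, significant at p < 0.01. `detect_surface_channel()`
scans boundaries from the probe top and maximizes within-block minus
between-block LFP correlation; `normalize_multiunit()` computes
`(FR − FR0)/(FR0 + s)` with `s` the pooled 10th percentile of baseline
rates.

The spike simulator draws the neuron as a dead-time renewal process whose
hazard is corrected so the realized rate equals the nominal rate exactly,
plus a uniform Poisson contaminant whose rate yields the requested
contamination fraction in expectation; amplitudes are Gaussian with
optional truncation at a detection floor (planting known missing-spike
fractions via the Gaussian tail mass).

## Problem sizes and numerical conventions

The test suite and the acceptance script use: 500 null sessions of 60
trials for behavioral calibration (2000 resamples each, enumeration-
backed); 2000 stationary units of 50 trials for shuffle calibration;
24×40 to 30×60 pixel synthetic movies at 70 Hz; units of 3,000–48,000
spikes for QC recovery. These sizes put every Monte Carlo estimate's
sampling error well inside the asserted tolerances while keeping a full
run in minutes. Time comparisons use a 1 ns guard against floating-point
ties; delays live on the 100 ms grid and samples on the 1 ms grid, so all
event times are exactly representable. Degenerate inputs are handled
explicitly: a single-combination delay grid yields a point-mass null and
p = 1; constant traces give all-zero dF/F with a warning; a silent violet
channel passes blue through unchanged; fewer than three channels make the
decay criterion indeterminate (configurable pass).

## Known limitations

The behavioral test inherits the per-trial boundary approximation
discussed above. The hemisphere subtraction assumes additivity and a
movement-gain ratio constant across epochs; it cancels bilateral signal
only as well as that ratio is estimated. The field-sign border precision
is limited by the smoothing radius. The contamination estimator's bias at
high contamination is quantified above. Serialization uses plain-text CSV
and float-32 TIFF containers; sessions reconstruct exactly because the
wheel is stored as its generating bout table rather than as samples.
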