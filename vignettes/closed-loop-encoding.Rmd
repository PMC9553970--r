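---
title: "Simulating and analyzing grasp-force-encoded stimulation feedback"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analyzing grasp-force-encoded stimulation feedback}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(graspstim)
```

## The system being modelled

In closed-loop sensory neuroprostheses, force measured at the fingertips of
a prosthetic hand is translated, in real time, into the amplitude of
electrical stimulation of somatosensory pathways, so that the user feels
graded touch when the prosthesis grasps an object. `graspstim` is a
desk-scale re-implementation of one such loop: a sensorized prosthetic hand
(real or virtual) is driven by one of two control schemes, fingertip force
is filtered and mapped to stimulation amplitude at 50 Hz, and object
discriminability is assessed from the *dynamics of the stimulation itself* —
when it starts, how fast it grows, and how strong it peaks.

Two control schemes are modelled, corresponding to the two task
configurations the package's presets reproduce:

* **Glove proportional** (`glove_proportional`): an instrumented glove on
  the intact contralateral hand proportionally commands the prosthetic
  aperture. The user therefore has intact proprioception of the *commanding*
  hand.
* **EMG threshold-velocity** (`emg_threshold_velocity`): surface EMG from
  residual ipsilateral muscles is enveloped and normalized to a maximum
  voluntary contraction (MVC); while the envelope is above a manual
  threshold, the hand closes at a constant 15 deg/s, otherwise it opens at
  30 deg/s — the behaviour of a normally-open body-powered prosthesis. The
  user has *no* proprioceptive access to the prosthetic aperture.

This asymmetry is the scientific crux: under glove control, hand aperture at
the moment stimulation begins is a reliable proxy for object size; under
constant-velocity EMG control, the only size cue in the stimulation channel
is the onset *lag*, which is corrupted by the variable delay between the
first flexion burst and the sustained grasp. The package's analysis module
quantifies exactly this contrast.

## The encoding schemes

Filtered fingertip force `F` is mapped to amplitude `A` each cycle.

**Linear.** Force is first normalized to its calibration range,
`F_n = (F - F_min) / (F_max - F_min)` clipped to [0, 1], then mapped
affinely, `A = F_n (A_max - A_min) + A_min`. Defaults: `F_min = 0.5` N,
`F_max = 10` N, `A_min = 1` mA, `A_max = 5` mA.

**Exponential.** `A = A_min exp(omega F)` for `F` above a one-unit
threshold and 0 otherwise, with `F` in *raw sensor units* and
`omega` an empirically assigned scaling factor in 0.005–0.025 per unit.
Because the map is unbounded, the commanded amplitude is capped at
`min(A_max, 6 mA)`; 6 mA is the stimulator's ganged-channel hardware
ceiling and is enforced everywhere. The sensor unit is a calibration of the
hand, not a physical constant; the simulator converts its newton-scale
forces with `sensor_scale` (default 20 units/N), which places ordinary
grasp forces in the 10^2–10^3-unit range that the printed `omega` window
implies.

Two interpretive choices deserve note. First, the linear formula alone
would command `A_min` at rest; both schemes are therefore gated by
`contact_threshold` (default `F_min`), so a stimulation *onset* exists and
onset-based features are well defined. Second, the exponential scheme's
one-unit threshold (0.05 N at the default calibration) sits inside sensor
noise, so the shared newton-scale gate is applied to it as well. The
exponential map is discontinuous at its threshold; the jump
(`encoding_jump()`) is reported, never smoothed.

## The real-time signal chain

All filtering is **causal** (single pass, zero initial state): the system
modelled ran in real time, so zero-phase filtering would be anachronistic.
The first ~0.5 s after onset is treated as filter settling in slope-based
checks.

* **Force**: 4th-order low-pass Butterworth, 4 Hz cutoff at 50 Hz
  (`lowpass_force()`). The digital (bilinear-transform) design has unity DC
  gain and exactly −3 dB at the prewarped cutoff; toward Nyquist its gain
  falls *below* the analog Butterworth magnitude because of frequency
  warping (at 20 Hz: 4.8e-5 rather than the analog 1.6e-3). The analytic
  digital magnitude is exposed as `butterworth_gain()` and is what the
  tests check measured tone gains against.
* **EMG**: raw 2000 Hz EMG is high-pass filtered at 10 Hz (2nd-order
  Butterworth; the order is configurable since only the corner is part of
  the modelled design), averaged over non-overlapping 20 ms bins — exactly
  one output sample per bin, hence 50 Hz — and rectified
  (`process_emg()`). Non-overlapping bins are adopted because they produce
  the 50 Hz rate exactly; a sliding average followed by decimation is a
  plausible alternative reading and is not asserted as the original
  intent.

**Order of averaging and rectification.** Taken literally, the processing
order is average-then-rectify, and `process_emg()` implements that as its
default (`rectify_after_average = TRUE`). On zero-mean EMG, however, the
20 ms bin mean is itself nearly zero-mean, so its absolute value is
half-normal: the envelope's per-bin density overlaps *any* threshold, and a
threshold-crossing controller driven by it chatters between closing and
opening. The conventional order — rectify at 2000 Hz, then average —
produces a concentrated envelope and clean threshold behaviour. The
simulator's control loop therefore uses `rectify_after_average = FALSE`
explicitly; the flag is honoured everywhere so both variants can be
studied. Since the MVC used for normalization is processed identically,
threshold semantics are preserved under either choice.

## What the synthetic-data generator emulates

Each trial simulates one object presentation at 50 Hz. Contact is a linear
spring: zero force until the closing hand reaches the object's
`contact_aperture`, then `stiffness` newtons per degree of further closure.
There is no damping, slip, or 3-D geometry (the physical task switched from
cubes to cylinders precisely to avoid corner slippage; that failure mode is
out of scope). The reported raw force is the maximum across three simulated
fingertip sensors receiving the same contact force plus independent
Gaussian noise, mirroring max-pooling over index/middle/ring sensors.

Default study conditions (chosen once; only their ordering is load-bearing
for the analysis):

| Quantity | Default | Rationale |
|---|---|---|
| Contact aperture, spheres/cubes XS/S/M/L | 20/30/45/60 deg | 15-deg steps spanning the hand's range |
| Contact aperture, cylinders S/M/L | 40/45/50 deg | graspable cylinder diameters; 5-deg steps |
| Stiffness soft/medium/hard | 0.05/0.15/0.45 N/deg | threefold steps, clearly ordered |
| Sensor noise SD | 0.05 N | small relative to the 0.5 N contact gate |
| Effective stiffness CV (per trial) | 0.10 | grip geometry and placement vary between presentations |
| Effective contact-aperture SD (per trial) | 2 deg | where on the fingers the object is met varies |
| Glove closing speed | 25 deg/s (CV 0.1) | unhurried volitional closure |
| EMG flexion-to-grasp delay (S2 presets) | mean 3 s, SD 2.5 s | seconds-scale variability of impaired ipsilateral control within a 20 s exploration window |

The per-trial stiffness and contact-aperture variability matter more than
they look: without them the simulated features have within-class variances
orders of magnitude below anything a physical grasp produces, and a
Mahalanobis classifier will happily decode class labels from sub-1%
discretization artifacts. Real presentations differ in grip geometry; the
lognormal stiffness factor and the contact-aperture jitter are the
generator's minimal representation of that.

**The EMG intent profile** is rectangular in amplitude but has two epochs: a
brief (0.25 s) initial flexion burst, then — after a truncated-normal delay
(`grasp_delay_mean`, `command_onset_jitter_sd`) — the sustained grasp.
The burst is what separates "onset of flexion" (the first threshold
crossing, from which onset lag is measured) from "onset of grasp"
(sustained closure). A single jittered rectangular epoch cannot inject
variance into the onset lag, because the lag clock starts at the threshold
crossing itself; the burst/delay structure is the mechanism that does.

What passing tests on these data do **not** show about real data: the
generator has no object slip, no EMG non-stationarity or fatigue, no
electrode-motion artifacts, no perceptual noise in the human observer, and
no day-to-day learning. Results here bound what the *stimulation channel*
carries, not what a person perceives.

## Feature extraction and statistics

Per trial: onset lag (command onset to first nonzero amplitude), peak
amplitude, rate of change of stimulation (onset to first peak), and hand
aperture at stimulation onset. Command onset is the first envelope
threshold crossing (EMG) or the first sample with aperture velocity below
−1 deg/s (glove). Trials without stimulation yield **null** features with a
reason code, never zeros; they are excluded from statistics and counted in
the report. The "first peak" is the first sample at which a 5-sample moving
average of the amplitude reaches 98% of its maximum: a literal
first-local-maximum rule is fragile to sensor-noise ripple on
ramp-then-plateau profiles, and an unqualified argmax lands arbitrarily
deep into the plateau and biases the rate low. A windowed-regression rate
(`rate_method = "regression"`) is available as an alternative.

The statistical battery mirrors standard practice for this task family:
exact upper-tail binomial tests against chance (1/K; upper-tailed because
the null is "no better than chance", with a two-sided option), MANOVA with
Wilks' lambda over the features, per-feature one-way ANOVA with Tukey-HSD,
and standard deviational ellipses (1 SD by default; the multiplier is a
parameter) whose pairwise overlap is decided by dense boundary sampling
with containment tests — tangency counts as overlap, and a degenerate
ellipse is treated as its major-axis segment. Whether size and compliance
should enter the MANOVA additively or with interaction is not settled by
the modelled design; both are exposed (`interaction =`), additive is the
default.

The **ideal observer** is a pooled-covariance nearest-centroid (equal-prior
linear discriminant) classifier on a configurable feature subset. It is the
simplest decoder consistent with "attend to the stimulation dynamics": it
lower-bounds the information in the channel and is not a model of human
perception — which is why its accuracies exceed the human accuracies
reported for the corresponding tasks. For EMG-scheme questions the feature
subset should exclude `aperture_at_onset_deg` (the prosthesis provides no
proprioception, so that feature is not perceptually available), and the
analyses here do so. A small ridge (1e-6 relative) keeps the pooled
covariance invertible when a feature saturates (e.g. peak amplitude pinned
at `A_max` for every hard object).

## Numerical and design choices

* 50 Hz is the canonical grid; EMG is generated at 2000 Hz and decimated by
  the binning chain, matching the modelled rates.
* Per-trial seeds derive from the session seed by a counter-based mix
  (`derive_seed()`), so any trial is reproducible in isolation and results
  never depend on execution order. All seeds stay below 2^31.
* Randomized schedules are a single uniform shuffle of the trial multiset;
  a block-randomized mode (one presentation of each object per block) is
  available behind `blocked = TRUE`, default off.
* The four-size physical task's uneven per-size counts (9/18/12/16) are
  taken as given; arbitrary per-object counts are supported and no
  intent is guessed.
* Test problem sizes: stochastic properties use 20 session-level seeds;
  Monte-Carlo monotonicity checks use 30 trials per condition; null
  calibrations of ANOVA/MANOVA use 200 draws. These sizes make the checks
  stable at the package's default noise levels.
* No multiple-testing correction is applied across the per-feature ANOVAs
  beyond Tukey's family-wise adjustment; the report says so explicitly.

## A worked session

```{r, eval = FALSE}
library(graspstim)

# 60 presentations of three cylinder compliances under EMG control,
# linear encoding
session <- simulate_preset_session("S2-physical-compliance", seed = 4)
report <- run_full_analysis(session)
cmd_report(report)
```

On this task the report shows the compliance signature: rate of change and
peak amplitude separate the three compliances (ANOVA p < 1e-40 at these
settings) while onset lag does not (p ≈ 0.6), and the per-compliance
ellipses for rate-based feature pairs are pairwise disjoint. Running the
same analysis on `"S2-physical-size"` shows the converse: onset lag is
swamped by flexion-to-grasp variability and size decoding from stimulation
features alone is statistically indistinguishable from the 33% chance
level, whereas `"S1-virtual-size"` (glove control) yields disjoint
aperture-at-onset ellipses and near-perfect size decoding.

## Known limitations

* The contact model is quasi-static and one-dimensional; compliant
  fingertip dynamics, slip, and multi-finger load sharing are absent.
* Sensor units, calibration limits, and perceptual amplitude ranges are
  free parameters; only their ordering and ranges are meaningful.
* The ideal observer's accuracy is an information bound, not a prediction
  of human performance; confusion structure (e.g. which sizes humans
  confuse) is outside its scope.
* The EMG model is a single-channel amplitude-modulated noise process; it
  reproduces envelope statistics, not motor-unit physiology.
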