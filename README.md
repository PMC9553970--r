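# graspstim

Simulation and analysis of a closed-loop sensory neuroprosthesis in which
prosthetic **grasp force is encoded into stimulation amplitude** in real
time, and object **size and compliance discriminability** is assessed from
the dynamics of the stimulation itself.

## The problem

When a prosthetic hand grasps an object, fingertip force can be fed back to
the user as graded electrical stimulation of somatosensory pathways. Whether
the user can then tell objects apart depends on which physical properties
survive the journey into the stimulation channel:

* **when** stimulation starts (onset lag after the grasp command — a size
  cue under constant-velocity closure),
* **how fast** it grows (rate of change — a compliance cue, since stiffer
  objects build force faster at fixed closing speed),
* **how strong** it peaks (peak amplitude), and
* **where the hand is** when it starts (aperture at stimulation onset — a
  size cue, but only perceivable when the commanding hand has
  proprioception, as with contralateral glove control).

`graspstim` simulates 50 Hz grasp trials against object sets of varying
size/compliance under two control schemes — contralateral data-glove
proportional aperture control, and EMG threshold-crossing constant-velocity
control (close at 15 deg/s above threshold, open at 30 deg/s below) — and
implements the full loop and analysis around them.

## The core mappings

Filtered force `F` (4th-order causal Butterworth, 4 Hz cutoff, 50 Hz) is
mapped to amplitude `A` each cycle by one of two schemes:

* linear: `F_n = (F − F_min)/(F_max − F_min)` clipped to [0, 1], then
  `A = F_n (A_max − A_min) + A_min`;
* exponential: `A = A_min e^{ωF}` for `F` above a sensor-unit threshold,
  else 0, with `ω ∈ [0.005, 0.025]` per sensor unit.

All commanded amplitudes are capped at the 6 mA ganged-channel hardware
ceiling; pulse-train parameters are validated against the stimulator's
operating ranges (1–300 Hz, 50–1000 µs, 60 µs interphase).

The statistical battery: exact (summation-based) upper-tail binomial tests
against chance (1/3 or 1/4), MANOVA (Wilks' Λ), per-feature one-way ANOVA
with Tukey-HSD, standard deviational ellipses with a boundary-sampling
overlap test, and a pooled-covariance nearest-centroid ideal observer
producing confusion matrices.

## Worked example

Sixty presentations of three cylinder compliances (all medium size) under
EMG control with linear encoding:

```r
library(graspstim)
session <- simulate_preset_session("S2-physical-compliance", seed = 4)
report  <- run_full_analysis(session)
cmd_report(report)
```

```
== Object compliance discrimination ==
classes: 3  chance: 33%
trials: 60 used, 0 null

-- Ideal observer confusion matrix (rows = true class) --
       hard medium soft
hard     10      0    0
medium    0     10    0
soft      0      0   10
overall accuracy: 100.0% (chance 33%)
  hard: 10/10 correct, exact binomial p = 1.694e-05
  ...
-- MANOVA (Wilks) --
  compliance_class: lambda = 0.0027, F(8, 108) = 248.55, p = 6.985e-66

-- Per-feature one-way ANOVA --
  onset_lag_s: F(2, 57) = 0.51, p = 0.6012
  peak_amp_mA: F(2, 57) = 1065.15, p = 7.163e-46
  rate_mA_per_s: F(2, 57) = 1225.39, p = 1.454e-47
  aperture_at_onset_deg: F(2, 57) = 80.58, p = 2.441e-17
```

Reading: at fixed closing velocity, the **rate of change** and **peak** of
stimulation cleanly separate the three compliances (stiffer objects build
force faster and higher), while the **onset lag** carries nothing (p ≈ 0.6)
— its variance is dominated by the flexion-to-grasp delay of impaired
myoelectric control. The observer's 100% is an information bound on the
channel, not a prediction of human accuracy. Running the same analysis on
`"S2-physical-size"` shows size decoding from stimulation features pinned
at the 33% chance level, whereas `"S1-virtual-size"` (glove control) gives
disjoint per-size aperture-at-onset ellipses and near-perfect size
decoding — the central control-scheme contrast the package exists to
reproduce.

A batch-friendly CLI wrapping the same functions ships in
`inst/cli/graspstim.R`:

```sh
Rscript inst/cli/graspstim.R presets
Rscript inst/cli/graspstim.R simulate --preset S1-virtual-size --seed 7 --out run1
Rscript inst/cli/graspstim.R analyze --out run1
Rscript inst/cli/graspstim.R report  --out run1
```

Run directories are self-describing (config + hash, per-trial seeds,
per-file checksums in `manifest.json`); simulation and analysis are fully
deterministic given the master seed.

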