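---
title: "Methods: multi-sensor analysis of roller-ski skating sessions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-sensor analysis of roller-ski skating sessions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skifuse)
```

## The problem

Cross-country ski skating on varying terrain is interval exercise in
disguise: even a session held at a nominally constant "intensity" cycles
the cardiovascular system, the working muscles and the movement technique
through large terrain-driven swings.  Quantifying those swings requires
fusing very different sensors — chest/wrist/ski inertial units (256 Hz),
pole force transducers (100 Hz), optical motion capture (200 Hz), a heart
rate monitor (1 Hz), mixing-chamber gas exchange (10 s values) and
near-infrared muscle oximetry — onto one session clock, detecting movement
cycles and gear (sub-technique) choices, timing pole and ski ground
contacts, partitioning propulsive power between poles and skis, and finally
reducing everything to statistics that can be compared between a
low-intensity (LI) and a high-intensity (HI) session.

skifuse implements that full chain as a tested R pipeline.  Because raw
recordings of this kind are rarely public, the package treats the synthetic
session generator as a first-class module: it produces every stream the
laboratory setup records, together with the ground truth (cycle
boundaries, gear labels, contact events, true centre-of-mass velocity,
per-cycle power, clock offsets), so each downstream stage is falsifiable.

## Session protocol

A session is `laps` identical laps (default 7 × 180 s = 21 min), each a
fixed sequence of four terrain segments: a moderate ascent (5 %), a nearly
flat stretch (2 %), a steep ascent (12 %) and a simulated downhill in
which skiers hold a rope in a tucked position.  Segment durations and
treadmill speeds are a packaged fixture (`protocol_default.yaml`;
durations 60/50/40/30 s, LI speeds 12.6/19/10/20 km/h, HI speeds
16.9/25/13/20 km/h).  The fixture is calibrated so that the time-weighted
mean speed — with the downhill *display* speeds of 30 (LI) and 35 km/h
(HI) substituted for the rope-assisted 20 km/h treadmill speed — is
16.7/21.3 km/h and the session distance 5.8/7.5 km; the per-segment values
themselves are an approximate, internally consistent choice, flagged as
such.  Windows are half-open `[start, end)` on a clock starting at 0 s, so
1 Hz binning is unambiguous; inclines are stored as grade fractions.

## Synthetic sessions: what is emulated

`generate_session()` draws every stochastic element from one RNG seeded
per session, so recordings are bit-reproducible.

* **Gear schedule.**  Terrain drives gear: G3 on the moderate ascent, G4 on
  the flat, G2 on the steep ascent (with a configurable G3 fraction, default
  0.4, at HI — skiers hold G3 longer on steep terrain at race pace), and
  "other" (tuck/transitions) on the downhill.  Cycle rates are fixed per
  gear and intensity (G2 56/66, G3 46/54, G4 34/41, other 25 cycles/min),
  values typical of elite treadmill skating.  Transitions sit at segment
  boundaries with optional jitter (default 0; the real transition timing
  within a segment is unknown).
* **Chest sway.**  Each cycle is one period of mediolateral sway starting
  at the "left-position" minimum.  G3 is near-sinusoidal, G4 carries a
  strong 2nd harmonic (two pushes per sway cycle), G2 alternates its
  amplitude every other cycle, and "other" is a weak 25-cpm rocking — weak
  but periodic, so that "other" is a real, learnable class rather than a
  rejection bucket, while a truly aperiodic signal still yields no cycles.
  Harmonics use even (cosine) terms only, which keeps the waveform minimum
  exactly on the cycle boundary.
* **Contacts.**  Within each poling cycle, pole contact occupies
  30–38 % of the cycle and ski contact 50–62 % (always longer than the
  poling), starting at fixed phase offsets, with the left ski half a cycle
  after the right.  The injected signatures mirror what the detectors
  operate on: a decaying 45 Hz vibration burst whose first peak marks
  initial pole contact, a sharp acceleration peak at the wrist
  angular-speed minimum for terminal pole contact, a final pitch-rate peak
  before a long (< 30 deg/s) quiet phase for initial ski contact, and a
  negative vertical-acceleration peak at its end.  Event times are snapped
  to the 256 Hz grid.
* **Power.**  The true CoM velocity oscillates about the belt speed;
  markers for a five-segment body model and for pole tip/grip are placed
  so that the mass-weighted combination reproduces that CoM exactly (plus
  0.3 mm optical noise).  Pole axial force is a half-sine per push with
  per-gear peak force (200/150/75 N for G2/G3/G4) calibrated to give a
  pole share of the work rate of roughly 60 % (G3), 65 % (G4) and 40 %
  (G2); the peak force declines 2 %/lap, emulating the reported gradual
  shift of propulsion toward the skis; at HI the peak force rises only
  3 % — the faster CoM supplies the rest — keeping the relative
  distribution nearly intensity-independent.  Markers exist on odd laps
  only, as in a motion-capture setup that records every second lap.
* **Physiology.**  Heart rate, oxygen uptake and tissue saturation follow
  first-order kinetics toward terrain-dependent setpoints (time constants
  25/30/20 s; lap 1 starts from rest).  At HI the heart-rate *setpoint*
  additionally ramps at 0.35 %-points of maximum per minute
  (cardiovascular drift).  Applying drift to the setpoint rather than as a
  per-step additive term makes the drift accumulate linearly, so the
  lap-7-minus-lap-2 change recovers 15·(drift rate) and parameter-recovery
  tests are exact on average.  TSI baselines are 68 % (arm) and 75 %
  (leg), with workload dips that are larger for the arm and 1.6× larger at
  HI.
* **Clocks.**  Inertial units run on their own clocks: a 10 s calibration
  window precedes the session, three synchronisation jumps (vertical
  spikes at master times −8/−6/−4 s) appear on every IMU, and each IMU
  carries a uniform ±0.25 s offset (snapped to its sample grid).  All
  other streams are recorded on the master clock.

What the generator does *not* emulate: biomechanically realistic limb
trajectories, force-shape variability, soft-tissue artefacts, sensor
drift/dropout, HR variability structure, or within-segment gear switching.
Tests passing on synthetic data therefore demonstrate the correctness and
calibration of the algorithms under the stated signal model, not
field-readiness on arbitrary real recordings.

## The analysis chain

1. **Alignment** (`align_stream`): jumps are detected on the vertical
   accelerometer as peaks above 5 median absolute deviations with a 0.5 s
   refractory gap (both configurable; the threshold is a robust default,
   not a measured property), and the mean detected-vs-expected jump time
   sets the clock offset.
2. **Cycles** (`detect_cycles`): the mediolateral channel is smoothed with
   a Gaussian kernel (σ = 0.15 s) and cycle starts are local minima with
   topographic prominence above 0.3 signal SDs.  Both parameters are
   tunable; the defaults keep 256 Hz noise out while passing 20–120
   cycles/min sway.
3. **Classification** (`train_subtech_model`/`classify_subtech`): a
   12-dimensional per-cycle descriptor (per-axis means and variances,
   dominant-frequency power ratio, 2nd-harmonic ratio, half-cycle RMS
   asymmetry, amplitude asymmetry against the following cycle — the G2
   discriminator — duration, mediolateral range) feeds a radial-kernel
   SVM (one-vs-one, features standardised from the training split).  The
   feature set is this package's design choice; the classifier family is
   the field's standard for IMU gear recognition.  Cycle length and rate
   follow from boundaries and belt speed, with `CL·CR/60 = speed` exact by
   construction.  A manual-correction hook (`apply_label_overrides`)
   substitutes reviewed labels verbatim.
4. **Contacts** (`detect_pole_contacts`/`detect_ski_contacts`): pole
   initial contact = first acceleration-magnitude peak after the 20–60 Hz
   vibration energy (20 ms moving SD) exceeds 4 baseline MADs; terminal =
   acceleration argmax within ±75 ms of the angular-speed minimum.  Ski
   contacts use low-pitch-rate phases (< 30 deg/s for ≥ 100 ms): initial =
   last preceding pitch-rate peak, terminal = deepest negative
   vertical-acceleration peak at the phase end.  Onsets within the
   previous push's terminal refractory are absorbed — the terminal spike
   itself excites the vibration band.  All thresholds are exposed as
   arguments; the defaults are stated bounds made operational.
5. **Power** (`session_power`): CoM from the segment-parameter table,
   velocity by central differences (one-sided at block edges; an optional
   Butterworth low-pass is applied to chord-detrended positions — off by
   default because per-cycle averaging already suppresses marker noise,
   and zero-phase filtering of kilometre-scale coordinates rings at block
   edges), pole direction from tip/grip markers, instantaneous power as
   the force–velocity dot product per side, and the treadmill work rate
   `P = m g v (sin θ + μ cos θ)` with μ = 0.016.  Air resistance and
   kinetic-energy fluctuation terms are excluded (constant-speed indoor
   treadmill); downhill cycles are excluded from the partition (the rope
   makes the work rate ill-defined), and cycles without ≥ 90 % force-grid
   coverage by marker data stay missing — interpolation never bridges
   unmeasured laps.
6. **Master timeline** (`build_master_timeline`): one row per session
   second; heart rate and oxygen uptake as % of the individual maxima
   (10 s chamber values step-held before the merge; a 30 s moving average
   is provided for plotting only), TSI reduced with a 2 s window,
   cycle-level quantities broadcast to the seconds their cycle spans, and
   missing measurements kept as `NA` so aggregation can never mistake
   absence for zero.

## Summary statistics and tests

Terrain-dependent fluctuation is the mean over laps 2–7 of the within-lap
peak-to-minimum span of a %-of-max series (lap 1 starts from rest and is
excluded); time-dependent change is the difference of within-lap means,
laps (2, 7) for physiological and (1, 7) for biomechanical/power series.
Both are computed on the raw 1 Hz series without additional smoothing.
For TSI the "% of max level" basis is the per-session maximum (a
configurable choice; a resting calibration value would also be
defensible).  Grouped means drop any gear×segment×lap exposure shorter
than 6 s.  Session deltas report HI−LI differences, as %-points for
percentage-scaled variables and with an integer percent change relative to
the LI mean for ratio-scaled ones.

Paired comparisons gate on Shapiro–Wilk normality of the differences at
α = 0.05: paired t-test if not rejected, otherwise Wilcoxon signed-rank
(zeros dropped, exact distribution for n ≤ 25 without ties); all-zero
difference vectors short-circuit to a flagged degenerate result.  The
two-way repeated-measures ANOVA tests each within-subject effect against
its own subject-by-effect stratum (`aov` with `Error(subject/(A*B))`);
no sphericity correction is applied by default — Greenhouse–Geisser
epsilons are available as an option via orthonormal-contrast projection.
Tukey post-hoc comparisons use the studentised range with the effect's
stratum mean square.

## Numerical choices and degenerate inputs

Reported one-decimal quantities use half-up rounding.  Constant signals
yield no cycles (prominence is zero); zero-duration cycles, non-unit pole
directions, non-positive work rates and unbalanced ANOVA designs raise
errors rather than propagate nonsense.  Effects whose sum of squares is
numerically zero report F = 0, p = 1 instead of 0/0 noise.  Boundary
matching between detected and reference cycles uses the cycle midpoint, so
millisecond boundary jitter cannot slip a cycle into its neighbour's slot.

## Problem sizes

The packaged studies run at desk scale: the classifier benchmark uses 20
synthetic sessions (≈ 18,000 labelled cycles, 80/20 split), detector
precision is measured on one full session per contact kind (≈ 1,500
events per detector), fluctuation statistics are validated against
brute-force scans on 1,000 random series, drift recovery uses 20 seeds,
and the paired-test calibration 1,000 null replicates.

## Known limitations

The classifier is trained and evaluated on the generator's signal model;
transfer to real device recordings would require retraining and likely a
richer feature set.  Contact detection assumes the signature morphology
described above.  The work-rate model omits inertial terms, so the
pole/ski partition inherits that approximation.  The TSI normalisation
basis and the per-segment protocol speeds are explicit assumptions, kept
configurable.
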