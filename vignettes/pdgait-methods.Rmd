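---
title: "Methods: simulating, detecting and classifying pressure-insole gait"
author: "pdgait authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating, detecting and classifying pressure-insole gait}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdgait)
```

## The problem

Parkinson's disease (PD) alters gait in ways that pressure-sensing insoles
can measure: steps shorten and slow, stance and double-support fractions
grow, and the walk ratio (step length over cadence) falls. Studies in this
area record bilateral insole data (16 pressure channels per foot at 100 Hz,
plus IMU channels, total force and centre of pressure) while participants —
PD patients in ON and OFF medication states, elderly controls (EL) and
adult controls (S) — walk 10 m straight-line segments at slow, normal and
fast self-selected speeds (WST tests) and perform a modified Timed Up and
Go (mTUG). Patients are scored with the MDS-UPDRS Part III motor
examination (33 items, total 0–132), binned into four severity levels:
normal 0–8, mild 9–32, moderate 33–58, severe 59–132.

`pdgait` implements the complete computational pipeline — gait-event
detection, extraction of 18 temporal and spatial features, a linear
mixed-model (LMM) significance screen with Bonferroni adjustment, and a
tree-ensemble classification bench for four tasks (PD vs non-PD; PD/EL/S;
ON vs OFF; mild vs moderate severity) — together with a synthetic recording
generator that carries exact ground truth, so every stage is testable
without access to any clinical recordings.

## The synthetic generator

`simulateRecording()` realises a straight-line walk from a `GaitProfile`:

* Heel-strike times alternate between feet; each step interval is drawn
  from a Gaussian with the profile's per-side mean (the left/right
  asymmetry ratio splits the overall mean) and step-to-step CV, truncated
  away from zero with a bounded retry count (100; exhaustion raises a
  simulation error).
* Step lengths are drawn the same way; walking stops when their cumulative
  sum reaches the nominal distance (default 10 m), so the true walked
  distance exceeds the nominal mark by less than one step — mirroring how
  participants overshoot a marked aisle.
* Within each stride, the stance interval occupies `stanceFraction` of the
  cycle; foot flat sits at 25% and heel rise at 70% of stance. These two
  template constants are fixed: they only have to make the four-event
  sequence detectable, not reproduce subject-specific loading.
* Pressure follows a double-bump loading template: heel channels (1–4)
  carry a fast-attack trapezoidal pulse from heel strike to heel rise,
  forefoot channels (10–16) one from foot flat to toe off, midfoot channels
  a small mid-stance bump. The template leads the event by 10 ms worth of
  ramp so that the first sample at/after a true heel strike is already
  positive while every earlier sample is exactly zero — giving the detector
  a clean, unambiguous crossing. Additive Gaussian noise (`noiseSD`,
  N/cm^2) is applied per channel and clipped at zero.
* IMU channels carry smooth periodic filler at the stride frequency. They
  exist for format fidelity only; no downstream stage reads them.

Double support is not an independent dial: with alternating symmetric
timing, a stance fraction `s` implies a double-support fraction `2s − 1`
(one interval after each heel strike), which matches the printed
double-support percentages to within a point. The profile stores the
derived value.

Condition profiles come from `makeProfile()`, which looks up the published
per-cell means and SDs (step duration and its left/right split, stance
percentage, step length) for each group, medication state and severity
level per test, and converts SDs to CVs. Combinations without a published
cell — severity together with medication state, or the normal/severe
levels, for which no recordings exist — raise a configuration error rather
than inventing numbers.

`simulateCohort()` adds the participant layer: each participant draws one
multiplicative random effect for step duration and step length (scaled by
`participantSD` times the cell CV) and an additive effect on the stance
fraction (SD 3 percentage points at `participantSD = 1`, matching the
spread of the printed stance percentages), shared across that participant's
recordings, tests and ON/OFF states — exactly the dependence structure the
repeated-measures mixed model downstream assumes. PD participants also
receive Part III totals (OFF about 12 points above ON, consistent with the
reported state means) whose bin supplies the severity label.

What the generator does *not* emulate: turning, gait initiation and
termination mechanics (the walk starts at the first heel strike, so the
opening cycle lacks its leading double support), freezing episodes,
left-right differences in loading shape, and any IMU realism. Passing
tests therefore validate the pipeline's arithmetic and robustness, not
clinical performance on real recordings.

## Event detection

`detectEvents()` runs a hysteresis state machine per foot over two region
loads (sums of the heel and forefoot channel groups). Heel strike fires
when the heel load crosses `onThreshold` upward from swing; foot flat when
the forefoot load also exceeds it; heel rise when the heel load falls below
`offThreshold` while the forefoot remains loaded; toe off when the forefoot
load falls below `offThreshold`. Design choices:

* Thresholds are fractions of each region's per-recording dynamic range
  (defaults 0.10 on, 0.05 off), which makes detection exactly invariant to
  rescaling all pressures and removes any dependence on sensor units.
* Candidate phases shorter than the debounce (50 ms) are rolled back: the
  event is deleted and the machine returns to its previous state. This is
  what makes isolated noise crossings harmless while leaving genuine
  phases (all ≥ 130 ms at the supported walking speeds) untouched.
* Events are timestamped at the first sample past the threshold, with no
  sub-sample interpolation: at 100 Hz the native resolution is 10 ms, and
  the suite's oracle tests bound noise-free detection error by one sample.
  This quantisation leaves a small systematic shortening of stance
  (~0.2 percentage points) that is well inside every stated tolerance.
* The straight-line analysis window comes from session metadata (the
  generator's ground-truth window in synthetic mode); video-synchronised
  windowing of real recordings is out of scope.

`segmentCycles()` keeps only complete strides: heel strike to next heel
strike containing the foot's own foot flat, heel rise and toe off in order
and exactly one contralateral heel strike. Incomplete leading/trailing
cycles are discarded rather than patched.

## The 18 features

With events in hand, `computeFeatures()` applies fixed conventions:

* A *step* is the interval from a contralateral heel strike to the next
  ipsilateral heel strike; the printed left + right step durations summing
  to the stride duration forced this convention over the alternatives.
* Stance is heel strike to toe off, swing its complement; single and double
  support are the per-cycle times with exactly one or both feet loaded,
  integrated from the two feet's stance episodes. Summed over a cycle they
  reconstruct the stride duration exactly whenever stance exceeds half the
  cycle (no flight phase) — one of the suite's exact identities.
* The four percentage features divide the mean support/phase times by the
  mean stride duration, so stance% + swing% = 100 holds exactly.
* `steps_number` counts step *intervals* (heel strikes minus one). This
  makes step length (distance/steps), cadence (steps per walking minute,
  first to last heel strike), velocity (distance/walking time) and walk
  ratio (step length in mm over cadence) mutually consistent estimators:
  a healthy walk generated with step length 0.65 m and cadence
  100 steps/min yields a walk ratio of 6.5 mm/step/min up to boundary-step
  truncation. Counting heel strikes instead would inflate cadence by
  n/(n−1) and deflate the walk ratio by ~12% at 10 m — inconsistent with
  the constancy of the walk ratio this quantity is meant to express.
* The walked distance is the session's true distance (nominal 10 m plus
  the overshoot). Because the aisle length is only known to within one
  step, `distanceSensitivity()` recomputes the four distance-dependent
  features at ±1 step; over the observed 14–23 step range the step-length
  change stays below 0.05 m, i.e. second-decimal stability.

## The mixed-model screen

For each feature, `lmmScreen()` fits
`feature ~ factor + (1 | participant)` on one test type's rows and tests
the whole fixed factor (up to three levels). Two methods are implemented:

* **Satterthwaite F on the REML fit (default).** Simulation during
  development showed the maximum-likelihood ratio test against the
  asymptotic chi-square reference is anti-conservative in the far tail at
  study-scale sizes (17 participants per level, two recordings): the
  family-wise error of the Bonferroni-adjusted screen inflated to ~0.09.
  The Satterthwaite-approximated F (equivalent to Kenward–Roger in these
  balanced designs, at a fraction of the cost) restores the nominal level
  and is therefore the default.
* **ML likelihood-ratio test** (`method = "lrt"`), kept for comparison.

P-values are Bonferroni-multiplied by the number of screened features (18)
within one (test type, factor) family — one adjusted p per feature per
test, the layout of the published significance tables — and flagged at
adjusted p < 0.05. Singular fits (zero participant variance, or designs
with one row per participant) fall back to a fixed-effects ANOVA F and are
flagged `degenerate` instead of failing the screen.

`selectFeatures()` keeps the significant features and, within any pair
correlated beyond `rCut = 0.90` (product-moment), drops the one with the
larger adjusted p (ties resolved toward the canonical feature order). If
nothing is significant the full set is returned with a warning so the
bench always has inputs.

The screen's calibration (family-wise type-I error under a simulated null,
power at a three-within-SD shift) is asserted by the test suite on the
feature-level cohort simulator `simulateFeatureTable()`, which draws the
18 features directly with a participant intercept at a chosen intraclass
correlation. Hundreds of replicate cohorts are needed for these studies,
and the screen's contract is the sample table, not the waveforms; the
waveform path is exercised end-to-end by the oracle-equivalence and
parameter-recovery suites instead. During development the screen's
family-wise error was measured at 0.0495 over 2000 null replicates
(per-test tail 0.0028 against the 0.05/18 nominal), i.e. the Satterthwaite
screen is calibrated to Monte-Carlo resolution.

## The classification bench

`runBench()` follows the published protocol: min–max scaling to [0, 1]
with ranges fitted on training rows only (held-out values pass through
unclipped; a constant column maps to 0), a stratified 80/20 split, feature
selection computed on training rows only, hyperparameters chosen by
stratified 5-fold cross-validated accuracy over a fixed grid, the chosen
model refit on all training rows and evaluated once on the held-out rows.
Accuracy is the headline metric; per-class recall is reported alongside.

* Random Forest and Extra Trees come from `ranger` (the latter with the
  extra-trees split rule, no resampling); AdaBoost is an in-package SAMME
  implementation over `rpart` trees, since no boosting-classifier package
  is available in the supported dependency set.
* The default grids (tree counts 200/500, `mtry` 2/4, node sizes 1/5;
  boosting rounds 30/60 at depths 1–3) total 110 candidate-fold
  evaluations, well under the documented budget of 1000 — the budget is a
  cap, not a target.
* Recordings are the sampling unit by default (a participant's ON and OFF
  recordings are distinct samples, matching how the study counts
  recordings); `participantGrouped = TRUE` switches to participant-level
  splitting for leakage-averse designs, since the original protocol does
  not state which was used. The distinction matters: with repeated
  recordings per participant, recording-level splits let tree ensembles
  recognise a held-out row's sibling recording in the training set and
  recover any participant-level label from it (we measured ~13 accuracy
  points above chance on label-free synthetic cohorts). Accuracies from
  recording-level splits should therefore be read as within-protocol
  performance, not generalisation to new participants.
* Classes smaller than the fold count reduce the fold count with a
  warning; fewer than two usable classes abort with a task-specific
  message.

The severity task restricts to mild and moderate — the only levels with
recordings — and the ON/OFF task drops rows without both states (controls,
infusion-pump patients).

## Numerical and degenerate-input choices

* Detection thresholds live on the region dynamic range; an all-zero
  (or constant) region yields an empty event list, not an error.
  Recordings shorter than one cycle yield empty cycle lists; feature
  extraction on them raises a named feature-extraction error.
* NaN pressures are a validation error — silence would corrupt thresholds.
* All simulation randomness flows through explicit integer seeds; cohort
  members get deterministic sub-seeds, so identical configs are
  bit-identical end to end (the run manifest's config hash plus seed pins
  a run).
* Gaussian draws for durations/lengths are truncated (retry bound 100) to
  keep them physical; positivity violations that persist raise a
  simulation error rather than looping.

## Problem sizes used by the test suite

The suite simulates at sizes chosen to make its statistical assertions
sharp yet quick on one core: 20-seed detection sweeps of ~50-stride walks,
recovery cohorts of 24 participants × 2 recordings per condition cell,
250 null and 120 power replicates at 17–20 participants per level for the
screen (the level and power themselves were characterised at 2000 and 200
replicates during development), and bench tables of 28–200 recordings. A
full `devtools::test()` run completes in roughly a quarter of an hour.

## Known limitations

* The generator's loading template is deliberately minimal; detector
  performance on real insole data (sensor drift, partial foot contact,
  shuffling gait, freezing) is untested by construction.
* Stride length is `2 ×` step length derived from the walked distance; the
  channel set carries no per-step spatial sensing, so per-stride spatial
  variability is not modelled or measured.
* Gait velocity uses the first-to-last heel-strike window; protocols that
  include terminal double support in the timed window will differ by a
  fraction of a stride.
* The published headline accuracies were obtained on a private clinical
  recording set; nothing here claims to reproduce them, and the bench's
  numbers on synthetic cohorts quantify the pipeline, not the disease.
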