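# pdgait

Pressure-insole gait analysis for Parkinson's disease (PD) studies:
differentiating patient groups, ON/OFF medication states and MDS-UPDRS
Part III severity levels from the spatiotemporal structure of straight-line
walking.

## What it does

Studies in this area record bilateral insole data (16 pressure channels per
foot at 100 Hz, IMU channels, total force, centre of pressure) while
participants — PD patients in ON and OFF states, elderly (EL) and adult (S)
controls — walk 10 m segments at slow/normal/fast pace (WST tests) and
perform a modified Timed Up and Go (mTUG). `pdgait` implements the full
computational pipeline:

* **Synthetic recordings with ground truth** — `makeProfile()` carries the
  published per-condition gait parameters (step duration, asymmetry, stance
  fraction, step length per group × state × severity × test);
  `simulateRecording()` / `simulateCohort()` emit 100 Hz insole recordings
  with exact event times, participant random effects and Part III scores.
* **Event detection** — `detectEvents()` annotates the gait-cycle sequence
  heel strike → foot flat → heel rise → toe off per foot with a hysteresis
  state machine over heel/forefoot region loads (thresholds as fractions of
  the dynamic range, 50 ms debounce); `segmentCycles()` keeps complete
  strides.
* **The 18 gait features** — `computeFeatures()` extracts step/stride
  durations, steps number, stance/swing and single/double support times,
  the four gait-cycle percentages (phase times normalised by the stride
  duration), and the distance-based spatials: velocity, step and stride
  length, cadence and the walk ratio
  `WR = step length [mm] / cadence [steps/min]` (≈ 6.5 in healthy adults,
  lower in parkinsonian gait).
* **Severity scoring** — `binSeverity()` maps Part III totals (0–132) onto
  normal (0–8), mild (9–32), moderate (33–58), severe (59–132);
  `controlSubsetTotal()` totals the six lower-extremity items 3.9–3.14.
* **Mixed-model screen** — `lmmScreen()` fits
  `feature ~ factor + (1 | participant)` per feature and test, tests the
  fixed factor (Satterthwaite F by default), Bonferroni-adjusts across the
  18 features and flags adjusted p < 0.05; `selectFeatures()` prunes
  correlated features (|r| > 0.9).
* **Classification bench** — `runBench()` runs min–max scaling, stratified
  80/20 split, grid-searched 5-fold CV and held-out accuracy for AdaBoost
  (in-package SAMME over rpart), Extra Trees and Random Forest (ranger) on
  the four tasks: PD/non-PD, PD/EL/S, ON/OFF, mild/moderate.
* **One-command pipeline** — `runAll(config.yaml)` chains everything and
  writes a deterministic, manifest-tracked run directory. A thin CLI lives
  at `inst/cli/pdgait.R`; file formats are documented in `FORMATS.md`.

## Worked example

Simulate a PD patient OFF medication walking the slow test, detect events,
and extract features:

```r
library(pdgait)

prof <- makeProfile("PD", medicationState = "OFF", testType = "WST_SLOW")
sim  <- simulateRecording(prof, seed = 42)
sim$truth
#> GroundTruth: 84 events, 20 steps, 10.54 m walked, window [0.00, 16.00] s

ev  <- detectEvents(sim$left, sim$right)
cyc <- segmentCycles(ev, segmentWindow(sim$truth))
ft  <- computeFeatures(cyc, ev, walkedDistance(sim$truth),
                       segmentWindow(sim$truth))
round(unlist(ft[c("step_duration_s", "stance_phase_pct", "swing_phase_pct",
                  "gait_velocity_mps", "step_length_m",
                  "step_frequency_spm", "walk_ratio_mm_per_spm")]), 3)
#>       step_duration_s      stance_phase_pct       swing_phase_pct
#>                 0.675                63.129                36.871
#>     gait_velocity_mps         step_length_m    step_frequency_spm
#>                 0.780                 0.527                88.823
#> walk_ratio_mm_per_spm
#>                 5.932
```

The extracted values sit where the OFF-state slow-walk condition puts them:
steps of ~0.68 s and ~0.53 m, stance ~63% of the cycle, velocity
~0.78 m/s, and a walk ratio of 5.9 — below the ~6.5 of healthy gait. A
Part III total of 42 bins as `binSeverity(42)` → `moderate`.

Cohort-level screening and classification:

```r
sessions <- simulateCohort(cohortDesign(nAdults = 10, nPD = 10),
                           tests = "WST_SLOW", seed = 1)
tab <- extractFeatureTable(sessions)
scr <- lmmScreen(tab, "group", testType = "WST_SLOW")
rep <- runBench(tab, benchConfig("PD_NONPD", testType = "WST_SLOW",
                                 seed = 1))
```

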