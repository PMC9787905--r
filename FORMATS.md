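# pdgait artifact file formats

All artifacts are plain text (CSV / JSON / YAML). Column spellings are fixed;
schema validation rejects files whose column set differs.

## Recording CSV (one file per foot)

Header (in order):

```
time_ms, p01..p16, ax, ay, az, gx, gy, gz, total_force, cop_x, cop_y
```

- `time_ms` — integer milliseconds, strictly increasing, 10 ms steps at the
  default 100 Hz sampling rate (1 ms jitter tolerated).
- `p01..p16` — the 16 pressure channels in N/cm^2, non-negative. The default
  sensor-region map used by the detector assigns channels 1–4 to the heel
  region and 10–16 to the forefoot region (configurable via
  `detectorConfig()`).
- `ax, ay, az` — acceleration in g; `gx, gy, gz` — angular rate in dps.
  Carried for format fidelity; no downstream stage reads them.
- `total_force` — computed total normal force in N, non-negative.
- `cop_x, cop_y` — centre of pressure in unitless insole coordinates.

The foot is not stored in the file; `readRecording()` takes it from a
`_left` / `_right` file-name suffix or an explicit argument.

## Events CSV

```
foot,event,time_s
```

`event` is one of `heel_strike`, `foot_flat`, `heel_rise`, `toe_off`; per
foot, events follow that cyclic order. Rows are stably sorted by
`(foot, time_s)` on read and write (canonical order for reproducible diffs).
Times are in seconds.

## Features CSV

Identifier columns, then exactly the 18 feature columns of
`gaitFeatureNames()`:

```
participant_id, group, medication_state, severity_level, test_type,
recording_index,
left_step_duration_s, right_step_duration_s, step_duration_s,
stride_duration_s, steps_number, single_support_time_s,
double_support_time_s, stance_time_s, swing_time_s, single_support_pct,
double_support_pct, stance_phase_pct, swing_phase_pct, gait_velocity_mps,
step_length_m, stride_length_m, step_frequency_spm, walk_ratio_mm_per_spm
```

## Session metadata JSON

One object per session:

```json
{
  "participant_id": "PD001", "group": "PD", "medication_state": "OFF",
  "severity_level": "moderate", "part3_total": 42,
  "control_subset_total": null, "test_type": "WST_SLOW",
  "recording_index": 1,
  "segment": {"start_s": 0, "end_s": 12.3,
              "nominal_distance_m": 10, "walked_distance_m": 10.42}
}
```

`group` is `S`, `EL` or `PD`; PD sessions carry `medication_state`
`ON`/`OFF`/`DCIP`, control sessions `null`.

## Pipeline config (YAML) and run manifest (JSON)

See `?runAll` for the config schema and
`inst/extdata/demo_config.yaml` for a worked example. The manifest records
the config MD5 hash, the seed, per-stage row/event counts and the relative
paths of every written artifact.
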