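# Demo pipeline configuration: a small cohort, two recordings per test.
seed: 7
cohort:
  adults: 4
  elderly: 2
  pd: 4
  pd_states: ["ON", "OFF"]
  profile_by: state
tests: [WST_NORMAL, WST_SLOW]
recordings_per_test: 2
noise_sd: 0.5
participant_sd: 1
detector:
  on_threshold: 0.10
  off_threshold: 0.05
  debounce_ms: 50
stats:
  factors: [group, medication_state]
bench:
  tasks: [PD_NONPD]
  classifiers: [random_forest]
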