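# Small end-to-end smoke configuration: 3 subjects, 30 trials per
# category, full continuous synthesis + preprocessing, 20 CV iterations.
seed: 7
cohort:
  n_subjects: 3
  method: full
  behavioral_accuracy: 0.9
session:
  n_trials_per_category: 30
  n_channels: 16
  fs_raw_hz: 500
preprocess:
  min_trials: 10
decode:
  n_iterations: 20
stats:
  n_permutations: 0
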