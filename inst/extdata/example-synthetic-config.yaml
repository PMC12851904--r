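# Example generator configuration (see ?synthetic_config for every field).
# Read with read_synthetic_config().
n_persons: 20000
rng_seed: 17
uptake_right_limit: 0.459
uptake_right_limit_dementia: 0.287
uptake_left_limit: 0.0
true_itt:
  mci: -0.015
  dementia: -0.013
  death_due_to_dementia: -0.085
baseline_outcome_risk:
  mci: 0.073
  dementia: 0.150
  death_due_to_dementia: 0.491
  death_other: 0.50
outcome_age_trend: 0.002
female_share: 0.546
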