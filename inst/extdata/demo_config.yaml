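seed: 20240101
out_dir: demo_output
simulate:
  "n": 500
outcomes:
  horizon_month: 12
impute:
  m: 5
  iterations: 5
estimate:
  outcome: ssfr_star
  n_reps: 200
  lambda: 0.125
  subgroup: none
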