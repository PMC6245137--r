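# Demo run configuration: small synthetic heart-failure cohort.
synthetic:
  n_patients: 1200
  frac_fast: 0.5
  n_planted: 10
  p_fast: 0.8
  p_slow: 0.4
  n_background: 40
  background_prevalence: 0.2
complication: heart_failure
q_fast: 0.25
q_slow: 0.75
min_frac: 0.01
min_diag: 5
median_mult: 2
alpha: 0.05
n_max: 12
n_grid: [7, 12, 20]
repeats: 2
test_frac: 0.2
threshold: 0.5
seed: 20260926
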