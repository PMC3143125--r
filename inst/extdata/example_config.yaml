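n_subjects: 1078
blood_group_freqs:
  O: 0.47
  A: 0.29
  B: 0.17
  AB: 0.07
rh_neg_freq: 0.08
outcome_prevalence:
  unaffected: 0.933209647495
  IUGR: 0.048237476809
  PE: 0.013914656772
  PE_IUGR: 0.004638218924
window_midweeks:
- 8.0
- 18.0
- 26.0
baseline_medians:
- 119.0
- 121.0
- 212.0
group_serum_multipliers:
  O:
  - 0.94
  - 0.97
  - 1.0
  A:
  - 1.01
  - 1.0
  - 1.0
  B:
  - 1.57
  - 1.45
  - 1.45
  AB:
  - 0.58
  - 0.8
  - 1.0
disease_mom_multipliers:
  unaffected:
  - 1.0
  - 1.0
  - 1.0
  IUGR:
  - 0.37
  - 1.38
  - 1.22
  PE:
  - 0.27
  - 1.71
  - 1.82
  PE_IUGR:
  - 0.25
  - 1.91
  - 1.62
log_sd: 0.4
covariate_params:
  bmi_mean: 24.0
  bmi_sd: 4.0
  age_mean: 29.0
  age_sd: 5.0
  smoking_prob: 0.12
  parity_lambda: 1.0
  ethnicity_levels:
  - eth1
  - eth2
  - eth3
  ethnicity_probs:
  - 0.7
  - 0.2
  - 0.1
covariate_effects:
  bmi: 0.01
  age: 0.0
  smoking: 0.0
  parity: 0.0
  ethnicity:
  - 0.0
  - 0.0
  - 0.0
dropout_prob: 0.1
baseline_by: window
seed: 1
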