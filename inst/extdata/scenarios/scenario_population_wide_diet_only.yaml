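type: scenario
name: population_wide_diet_only
start_year: 2011
diffusion_years: 5
population_policy:
  bmi_trend_damping: 0.05
  sbp_shift: 0.8
  fv_increase_share: 0.5
  smoking_prev_reduction: 0.0
  reduction_years: 5.0
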