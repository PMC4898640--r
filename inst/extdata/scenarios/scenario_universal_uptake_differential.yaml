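type: scenario
name: universal_uptake_differential
start_year: 2011
diffusion_years: 5
screening:
  target_fifths:
  - 1
  - 2
  - 3
  - 4
  - 5
  age_range:
  - 40.0
  - 74.0
  uptake: 0.5
  participant_risk_mix:
    low: 0.7
    mid: 0.25
    high: 0.05
  share_over_60: 0.3
  treatment_threshold: 0.1
  statin_uptake:
    high: 0.24
    mid: 0.17
  antihtn_uptake:
    high: 0.27
    mid: 0.2
  tchol_threshold: 5.0
  sbp_threshold: 135.0
  persistence: 0.8
  adherence: 0.7
  statin_tchol_reduction: 1.3
  antihtn_sbp_reduction: 10.0
  bariatric_bmi_threshold: 50.0
  bariatric_bmi_target: 30.0
  lifestyle:
    fv_threshold: 5.0
    fv_prob: 0.5
    pa_threshold: 5.0
    pa_prob: 0.5
    bmi_mult: 0.99
  cessation_rate: 0.1
  uptake_ses_differential: 0.9
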