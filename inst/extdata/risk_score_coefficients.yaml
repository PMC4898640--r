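S0:
- 0.935
- 0.965
age: 0.07
sbp: 0.012
tchol: 0.15
smoker_current: 0.55
smoker_former: 0.15
diabetes: 0.6
bmi: 0.015
deprivation: 0.08
ref:
  age: 55.0
  sbp: 130.0
  tchol: 5.0
  bmi: 27.0
  imd: 3.0
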