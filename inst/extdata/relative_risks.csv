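exposure,disease,type,level,ref,per,rr,ci_lo,ci_hi,floor
bmi,chd,continuous,,23,5,1.25,1.18,1.32,0.5
sbp,chd,continuous,,115,20,1.45,1.35,1.55,0.5
tchol,chd,continuous,,3.8,1,1.35,1.25,1.45,0.5
fv_portions,chd,continuous,,5,1,0.96,0.93,0.99,0.5
pa_days,chd,continuous,,5,1,0.97,0.94,1,0.5
diabetes,chd,categorical,1,,,1.9,1.6,2.2,0.5
smoking,chd,categorical,current,,,2.2,1.9,2.5,0.5
smoking,chd,categorical,former,,,1.25,1.1,1.4,0.5
ets,chd,categorical,1,,,1.25,1.1,1.4,0.5
bmi,stroke,continuous,,23,5,1.15,1.08,1.22,0.5
sbp,stroke,continuous,,115,20,1.6,1.45,1.75,0.5
tchol,stroke,continuous,,3.8,1,1.08,1,1.16,0.5
fv_portions,stroke,continuous,,5,1,0.95,0.92,0.98,0.5
pa_days,stroke,continuous,,5,1,0.97,0.94,1,0.5
diabetes,stroke,categorical,1,,,1.8,1.5,2.1,0.5
smoking,stroke,categorical,current,,,1.9,1.6,2.2,0.5
smoking,stroke,categorical,former,,,1.15,1,1.3,0.5
ets,stroke,categorical,1,,,1.25,1.1,1.4,0.5
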