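type: scenario
name: baseline
start_year: 2011
diffusion_years: 5
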