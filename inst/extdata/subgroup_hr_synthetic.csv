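name,hr,hr_low,hr_high
overall_population,0.63,0.49,0.82
asian_population,0.62,0.46,0.85
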