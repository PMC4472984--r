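# Experiment design for the 19-gene chickpea CaNAC dehydration screen
reference_gene: IF4a
control_treatment: water
stress_treatment: dehydration
tolerant_cultivar: ILC482
sensitive_cultivar: Hashem
fold_change_threshold: 2.0
alpha: 0.05
timepoints: [2, 5]
aggregate: per_replicate
test_scale: delta_ct
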