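"name","kind","age_low","age_high","observed","weight"
"cumulative_endometriosis_cases","cumulative_count",NA,NA,210000,1
"prev_15_19","age_specific_prevalence",15,19,0.003,1
"prev_20_24","age_specific_prevalence",20,24,0.01,1
"prev_25_29","age_specific_prevalence",25,29,0.02,1
"prev_30_34","age_specific_prevalence",30,34,0.028,1
"prev_35_39","age_specific_prevalence",35,39,0.028,0
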