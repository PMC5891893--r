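"age_low","age_high","count"
10,14,3243243.24324324
15,19,3145945.94594595
20,24,3048648.64864865
25,29,2951351.35135135
30,34,2854054.05405405
35,39,2756756.75675676
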