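# Example endocea configuration. Any key not set falls back to the base case.
model:
  discount_rate: 0.03
  p_recurrence: 0.222
  incidence_dysmenorrhea:
    ages: [12, 16, 30]
    values: [0.0008, 0.007, 0.0008]
    interpolation: linear
costs:
  visit_cost_dys: 7529
run:
  seed: 20180410
  horizon: 23
  n_psa: 10000
  wtp: 5.0e+6
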