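name: ev_specific_n4
kind: evidential_value
parameters:
  label: H_s
  region_A: [0.2, 0.3]
  region_B: [0.7, 0.8]
  n_A: 4
  n_B: 4
  weights: [0.5, 0.5]
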