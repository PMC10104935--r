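name: ev_vague_n4
kind: evidential_value
parameters:
  label: H_v
  region_A: [0.0, 0.5]
  region_B: [0.5, 1.0]
  n_A: 4
  n_B: 4
  weights: [0.5, 0.5]
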