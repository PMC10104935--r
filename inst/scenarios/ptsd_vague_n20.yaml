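name: ptsd_vague_n20
kind: bf
parameters:
  label: H_v
  region_A: [0.0, 0.5]
  region_B: [0.5, 1.0]
  n_A: 20
  n_B: 20
  s_A: 5
  s_B: 15
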