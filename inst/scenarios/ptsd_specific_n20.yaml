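name: ptsd_specific_n20
kind: bf
parameters:
  label: H_s
  region_A: [0.2, 0.3]
  region_B: [0.7, 0.8]
  n_A: 20
  n_B: 20
  s_A: 5
  s_B: 15
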