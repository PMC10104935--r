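name: bfda_n190
kind: bfda
parameters:
  n_per_group: 190
  effect_size_d: 0.4
  prior_scale_r: 0.7071067811865476
  upper_threshold: 3
  lower_threshold: 0.3333333333333333
  n_sims: 10000
  seed: 2024
  alternative: greater
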