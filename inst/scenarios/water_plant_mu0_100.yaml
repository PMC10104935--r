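name: water_plant_mu0_100
kind: sev
parameters:
  mu0: 100
  sigma: 10
  "n": 100
  alpha: 0.025
  xbar: 152
  mu1: 153
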