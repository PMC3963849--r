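# Reference one-class configuration: cover retention 0.9 without fire,
# 0.4 with fire, recruitment 0.1 into free space, fire certain below
# cover 0.2 and absent above 0.8.
stages:
  A_nf: 0.9
  A_f: 0.4
recruitment:
  a: 0.1
  mode: space_limited
fire:
  theta1: 0.2
  theta2: 0.8
  p_max: 1.0
  p_min: 0.0
simulation:
  seed: 1
  horizon: 5000
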