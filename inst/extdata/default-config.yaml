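params:
  alpha1: 0.2165
  alpha2: 0.01269
  alpha3: 3.3000000000000002e-07
  alpha4: 0.20999999999999999
  alpha5: 0.077016353395549478
  alpha6: 0.10000000000000001
  alpha7: 0.095000000000000001
  alpha8: 0.046209812037329684
  alpha9: 9.9999999999999995e-07
  alpha10: 0.033007008598092635
  alpha11: 0.0089999999999999993
  h: 0.01
  k1: 10
  k2: 1
  k3: 50
  M: 196000
  C0: 180000
  p: 760000
  q: 1000000
  tau: 1
  dt_hours: 8
solver:
  horizon: 100
scenario: all
injection_day: 3
observables:
  cell_diameter: 0.02
  packing: 1
synthetic:
  n_mice: 5
  days:
  - 6
  - 9
  - 12
  - 15
  - 18
  - 21
  - 24
  - 27
  - 30
  noise_sigma: 0.050000000000000003
  mouse_cv: 0.050000000000000003
sensitivity:
  'n': 1000
  span: 0.5
  dose_lower: 0.25
  dose_upper: 2
  alpha: 0.01
  output_every_dt: 3
  use_fit_ranges: yes
seed: 1
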