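alpha1: 0.2165
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
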