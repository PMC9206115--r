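k0: 0.08
k1: 4.0
k2: 2.2
k3: 0.4
k4: 0.135
k5: 0.5
k6: 0.5
k7: 0.018
k8: 0.5
k9: 0.4
k10: 0.11
alpha: 1.0
beta: 0.0
D_RT: 0.9
D_RD: 9.0
D_F: 0.09
sigma: 0.15
s: 2.0
f: 10.0
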