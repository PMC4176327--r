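model: conceptual
v_P: 1.0
v_A: 0.373663
K1: 0.45
K2: 4.392858
h: 4.0
c: 1.0
d1: 1.5
d2: 0.14
tau_P: 10.5
tau_A: 14.0
al_enabled: yes
amp_scale_P: 1.0
amp_scale_A: 1.0
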