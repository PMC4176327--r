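model: comprehensive
v_B: 1.4
v_P1: 1.2
v_P2: 1.2
v_C1: 0.8
v_C1r: 0.8
v_C2: 0.8
v_R: 1.2
K_B: 0.05
h_B: 2.0
K_E: 1.62
w_P1: 0.3
w_P2: 0.3
w_C1: 0.5
w_C2: 0.2
h_E: 4.0
K_R: 0.49
h_R: 4.0
a_E: 0.6
a_R: 0.4
d_B: 1.0
d_P1: 0.4
d_P2: 0.4
d_C1: 0.4
d_C2: 0.4
d_R: 1.2
tau_P: 9.399
tau_B: 2.0
tau_R: 0.75
tau_RC: 17.0
b_B: 0.0
b_P1: 0.0
b_P2: 0.0
b_C1: 0.0
b_C2: 0.0
b_R: 0.0
amp_scale_P: 1.0
amp_scale_A: 1.0
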