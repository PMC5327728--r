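# Mock (parental SW480 xenograft) parameter set, nondimensional units.
D_o: 0.01
D_g: 0.01
D_W: 0.004
D_WI: 1
D_N: 100
tau_o: 1
tau_g: 1
tau_og: 0.0416666666666667
tau_go: 1
alpha_W: 1
kappa_W: 5
kappa_WI: 1
mu_o: 1
mu_g: 1
mu_d: 1
mu_W: 2
mu_WI: 3
mu_N: 0.1
S_W: 7.5
a: 1.0e-8
b: 1
gamma_W: 1
gamma_N: 100
nu_NG: 10
nu_NO: 10
N_s: 2
alpha_N: 0.025
W_star: 5
N_star: 0.07
N_g_star: 0.1
S_x: 12
S_y: 12
S_z: 12
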