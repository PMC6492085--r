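# Simulation scenario preset (set1_a2-0_a3-0.5); keys mirror sim_scenario(); D, A row-major.
K: 5
n_per_study: 500
meas_times: [0, 0.25, 0.5, 1, 1.5, 2, 2.5, 3, 3.5, 4]
beta10: 1
beta11: 3
beta12: 2
beta21: 3
alpha2: 0
alpha3: 0.5
D: [1, 0.5, 0.5, 1.5]
A: [1, 0.5, 0.5, 1.5]
sigma_e2: 0.01
mu0: 3
sigma0: 0.5
log_lambda_cens: -0.426
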