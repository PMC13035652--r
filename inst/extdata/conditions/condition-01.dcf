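condition: 1
sampling_plan: simple
prevalence: 0.02
target_n: 1000
target_n_min:
target_n_max:
k: 30
delta_m: 0.8
delta_y: 0.5
rho_within: 0.4
tau2_delta_m: 0.1
tau2_delta_y: 0.1
tau2_rho: 0.02
missing_studies: 12
subpop_prevalence: no
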