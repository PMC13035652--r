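condition: 12
sampling_plan: stratified
prevalence: 0.5
target_n:
target_n_min: 26
target_n_max: 600
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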