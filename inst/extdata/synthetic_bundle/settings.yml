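cohort_size: 10000.0
entry_age: 16.0
exit_age: 81.0
cycle_length: 1.0
discount_rate: 0.035
threshold: 20000.0
psa_iterations: 2000.0
male_fraction: 0.5
seed: 42.0
high_level_width: 419.0
convergence_tol: 0.001
multiplier_scale: hazard
discount_first_cycle: yes
epidemiology_source: synthetic
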