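n_mirna: 40.0
n_mrna: 80.0
n_per_group: 3.0
frac_de_mirna: 0.3
lfc_de: 2.0
targets_per_mirna: 6.0
n_regulators: 3.0
frac_inverse_targets: 0.75
coupling_strength: 1.5
nb_dispersion: 0.1
mean_log_mu: 6.0
sd_log_mu: 1.5
lib_size_factor_range:
- 0.7
- 1.3
seed: 20.0
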