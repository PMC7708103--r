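# Example simulation configuration for the neomort CLI:
#   neomort run --config example_config.yaml --seed 1 --out-dir out/
# Unspecified fields keep the package defaults (see ?simulation_config).
n_clusters: 10
years: [2015, 2016, 2017]
deliveries_per_cluster_year: [300, 500]
sign_fidelity: 0.9
seed: 1
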