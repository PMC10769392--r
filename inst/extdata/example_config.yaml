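# Example pipeline configuration; any key from default_config() can be set
# here, and arguments to run_pipeline() override the file.
seed: 1
M: 5
sigma: 0.25
n_windows: 20
eqtl_n_pos: 30
eqtl_n_neg: 30
personal_n_genes: 4
personal_n_individuals: 40
stages: [simulate, peaks, consistency, motif, eqtl, personal, report]
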