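# Demonstration configuration: a small staged five-library experiment.
design:
  n_genes: 300
  gene_length_range: [200, 1500]
  n_libraries: 5
  library_depth: 50000
  de_fraction: 0.1
  fold_change_range: [8, 8]
  error_rate: 0.001
  adaptor_only_rate: 0.01
  n_read_rate: 0.00002
  catg_fraction: 0.95
  seed: 42
parameters:
  max_mismatch: 1
  fdr_threshold: 0.001
  log2_threshold: 1
  extreme_threshold: 10
  cluster_k: 4
  alpha: 0.05
annotation:
  n_terms: 30
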