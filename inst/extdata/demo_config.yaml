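simulate:
  n_samples_per_group: 25
  n_snps: 1200
  n_chromosomes: 3
  background_c: 0.01
  missing_rate: 0.01
  planted_windows:
    chrom: "2"
    start_snp_index: 150
    n_snps: 12
    delta: 0.5
  seed: 42
qc:
  max_missing_rate: 0.02
  hwe_alpha: 1.0e-7
  rel_cutoff: 0.75
  ld_window_snps: 50
  ld_step_snps: 5
  ld_r2_max: 0.2
scan:
  estimator: weir_cockerham
  smooth_window_snps: 9
  outlier_quantile: 0.99
  region_merge_gap_bp: 1000000
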