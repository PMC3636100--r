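# Default simulation scenario: two highly polygenic traits with ~1.2% of
# SNPs non-null in both. Usable directly with `run_pipeline()` or the
# `condfdr run --config` / `condfdr simulate --config` subcommands.
simulate:
  n_snps: 100000
  pi: [0.97, 0.009, 0.009, 0.012]
  sigma0_sq: [1, 1]
  sigma1_sq: [2, 2]
  rho3: 0
  inflation: [1, 1]
  ld_block_size: 5
  ld_r2: 0.8
  genic_fraction: 0.5
  seed: 42
gc:
  min_intergenic: 100
  statistic: chisq
condfdr:
  grid_step: 0.1
  min_subset_size: 100
loci:
  fdr_threshold: 0.05
  r2_threshold: 0.2
mixfit:
  n_restarts: 5
  seed: 1
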