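# Bundled demo: synthetic genome at desk scale (1 chromosome x 1 Mb,
# ~10,000 CpGs, 10 treated + 2 untreated cells) under the study conditions
# the calling scheme assumes.
seed: 1
window_size: 1000
synthetic:
  n_chrom: 1
  chrom_len: 1000000
  cpg_density: 10
  base_rate: 0.0005
  class_rates:
    L1: 0.0025
    ERVK: 0.0025
  conversion_eff: 0.8
  background_rate: 0.0115
  coverage_mean: 5
  stages:
    zygote: 4
    two_cell: 4
    four_cell: 2
  n_untreated: 2
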