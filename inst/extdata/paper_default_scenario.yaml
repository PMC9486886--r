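genome:
  n_groups_per_subgenome: 25
  group_length: 2.0e6
snp:
  density: 1.0e-3
  decoy_fraction: 0.3
sequencing:
  depth: 30
  error_rate: 0.002
  ref_bias: 0.05
meiosis:
  co_count_probs:
    "1": 0.5
    "2": 0.5
analysis:
  window: 1.0e5
  threshold: 0.5
  calibrate: true
  min_run: 3
  min_snps_per_window: 2
cohort:
  n_na3n: 10
  n_ga3n: 10
  n_ca3n: 10
seed: 20220901
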