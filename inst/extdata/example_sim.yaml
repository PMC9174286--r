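# Example simulation configuration for `ppr_main("simulate", ...)`.
# Mirrors sim_config() field for field: populations are processed in order,
# so parents and admixture sources must precede their descendants.
n_snps: 5000
seed: 11
n_chrom: 22
freq_range: [0.05, 0.95]
pops:
  - label: Levant_N
    F: 0.08
    n: 12
  - label: Iran_N
    F: 0.08
    n: 12
  - label: Mbuti
    F: 0.3
    n: 12
  - label: Target
    sources: [Levant_N, Iran_N]
    weights: [0.6, 0.4]
    F: 0.02
    n: 0
pair:
  source: Target
  relatedness: unrelated
  depth: 5
  error: 0.001
  damage: 0.02
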