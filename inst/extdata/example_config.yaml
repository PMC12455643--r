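# Example simulator configuration for `alevar` (see ?ale_config).
# Keys are ale_config() arguments; omitted keys keep their defaults.
n_transfers: 20
ploidy: 10
bottleneck_size: 10000
od_initial: 0.05
od_final: 2.0
mutation_rate: 3
sequencing_depth: 100
fp_rate: 20
salt_schedule:
  mode: stepwise
  start_mM: 200
  step_mM: 50
  max_mM: 400
driver_genes:
  gene_05: 0.25
  gene_17: 0.25
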