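# Example sigregulon pipeline configuration.
paths:
  counts: out/counts.tsv
  samples: out/samples.tsv
  exclusions: exclusions_example.tsv
  out_dir: out
thresholds:
  fdr_threshold: 0.05
  lfc_threshold: 1
simulation:
  n_genes: 3000
  n_replicates: 3
  dispersion: 0.05
  n_per_class: 100
  effect_log2: 2
  planted_condition: heat
seed: 1
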