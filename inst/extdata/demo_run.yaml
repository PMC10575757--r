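# Reduced-scale demonstration of the full workflow on the bundled
# 4-cluster synthetic campaign (runs in a few minutes on one CPU).
seed: 5
top_k_frequency: 5
top_k_enrichment: 5
profile_top_n: 200
simulation:
  n_clusters: 4
  reads_per_round: 10000
  rounds: 2
  seed: 11
generative:
  hidden_units: 32
  max_epochs: 12
  cv_folds: 3
  sample_n: 600
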