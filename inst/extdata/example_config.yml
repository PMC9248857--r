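# Example organsort pipeline configuration.
# Keys override the defaults from default_pipeline_config(); anything
# omitted keeps its reference value (PCC 0.8, SCC 0.6, perplexity 50,
# theta 0.5, FC 2, q 0.05, floors 0.9/0.95, 10-fold CV, 2/3 split).
seed: 11

# either a `simulate` block ...
simulate:
  n_proteins: 1000
  contamination_rate: 0.05
  noise_sd: 0.2

# ... or an `input` block pointing at TSV files:
# input:
#   quant: quant.tsv
#   references: references.tsv
#   domains: domains.tsv
#   complexes: complexes.tsv

markers:
  pcc_rep: 0.8
  pcc_cond: 0.8
  scc_cond: 0.6

classify:
  grid_preset: coarse
  precision_floor_cluster: 0.9
  precision_floor_neighborhood: 0.95

complexes:
  pcc_cutoff: 0.8
  n_null_pairs: 500
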