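# Example configuration for inst/scripts/run-analysis.R: a fast full run
# on a generated study dataset. Replace the `synthetic:` block with
#   traits: path/to/species_traits.csv
#   tree: path/to/tree.nwk
# to analyze real data (column layout: inst/extdata/species_table_columns.csv).
synthetic:
  n_species: 67
  n_families: 24
  seed: 1
analyses: [asr, phylanova, pgls, brownie, mating]
aggregation: median
fast: true
seed: 1
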