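# Quick-demo pipeline configuration: overrides the package defaults
# (see default_config()) to a 60-city frame with a 40-word lexicon.
seed: 7
simulate:
  n_cities: 60
  doc_length: 2000
  vocab:
    n_seeds: 10
    n_synonyms: 30
    n_distractors: 20
    n_filler: 300
  cooccurrence:
    n_sentences: 2000
cbow:
  dim: 40
  epochs: 10
diagnostics:
  n_perm: 199
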