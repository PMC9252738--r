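Synthetic fixtures (no experimental data):

- synthetic_scores_dope.tsv / synthetic_scores_rosetta.tsv: synthetic
  model-score tables for a notional 18-design single-loop library, used to
  regression-test score ingestion and dense ranking (including a tied DOPE
  pair and one design lacking a Rosetta score). Values are invented on the
  scale typical of such scores; they do not derive from any modelling run.
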