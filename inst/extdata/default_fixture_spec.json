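{
  "seed": 2023,
  "n_features": 6,
  "instances_per_feature": [2, 4],
  "synonyms_per_term": [0, 2],
  "n_datasets": 3,
  "rows_per_dataset": 25,
  "corruption": {
    "p_synonym_swap": 0.4,
    "p_case_mangle": 0.2,
    "p_typo": 0,
    "p_missing": 0.05,
    "p_duplicate_column": 0.1,
    "p_unknown_term": 0
  },
  "feature_names": ["dose", "time point", "tissue", "ethnicity", "compound", "sex"]
}
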