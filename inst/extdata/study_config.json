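{
  "setups": [1, 2, 3, 4],
  "m_grid": [1],
  "n_replicates": 100,
  "sample_n": 3000,
  "population_n": 1000000,
  "T": 4,
  "master_seed": 1,
  "estimators": ["msm", "tvt-outcome", "tvt-cs", "gt-did"],
  "control_types": ["never", "notyet"],
  "include_g1": true
}
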