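{
  "heterogeneous_selection": {
    "filter_strength": null,
    "migration_rate": 0.02,
    "n_env_patches": 5,
    "founder_richness": 35,
    "founder_concentration": 1.0
  },
  "homogeneous_selection": {
    "filter_strength": 0.4,
    "migration_rate": 0.02,
    "n_env_patches": 1,
    "founder_richness": 60,
    "founder_concentration": 3.0,
    "niche_size": 3
  },
  "dispersal_limitation": {
    "filter_strength": null,
    "migration_rate": 0.02,
    "n_env_patches": 1,
    "founder_richness": 25,
    "founder_concentration": 0.3
  },
  "homogenizing_dispersal": {
    "filter_strength": null,
    "migration_rate": 0.97,
    "n_env_patches": 1,
    "founder_richness": 25,
    "founder_concentration": 0.3,
    "source_richness": 30,
    "source_concentration": 0.3
  },
  "drift_diversification": {
    "filter_strength": null,
    "migration_rate": 0.5,
    "n_env_patches": 1,
    "local_concentration": 200
  }
}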