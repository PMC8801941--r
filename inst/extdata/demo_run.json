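{
  "seed": 7,
  "out_dir": "demo_out",
  "stages": {
    "simulate": {
      "n_genes": 800,
      "n_cells_per_cluster": {"Lc": 200, "Im": 80},
      "conditions": ["Nt", "O50t"],
      "mito_genes": 10,
      "mito_fraction": 0.05,
      "modules": [
        {"name": "Senescence", "n_genes": 25, "loading": 0.42,
         "latent_factor_id": "f", "condition_mean_shift": {"O50t": 1.5}},
        {"name": "Androgen", "n_genes": 25, "loading": -0.42,
         "latent_factor_id": "f"}
      ]
    },
    "qc": {"min_features": 20, "max_features": 800,
           "max_percent_mt": 20, "min_cells_per_gene": 3},
    "score": {"signatures": "demo_out/modules.gmt"},
    "screen": {"target": "Senescence", "cluster": "Lc", "condition": "Nt",
               "r_min_pos": 0.3, "r_max_neg": -0.3},
    "shift": {"target": "Senescence", "cluster": "Lc",
              "condition_a": "Nt", "condition_b": "O50t"},
    "de": {"cluster": "Lc", "condition_a": "O50t", "condition_b": "Nt"}
  }
}
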