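{
  "recipe": "ripley",
  "seed": 1,
  "spatial": {
    "model": {"model_kind": "clustered_segregated", "window_nm": [1000, 1000],
              "n_parents": 20, "parent_radius_nm": 30,
              "n_offspring_green": 10, "n_offspring_red": 10},
    "radii_nm": [10, 20, 30, 40, 50, 75, 100, 150, 200],
    "n_sim": 199, "confidence": 0.95, "edge_correction": "isotropic"
  },
  "output": {"dir": "out_ripley"}
}
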