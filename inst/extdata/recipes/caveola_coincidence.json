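{
  "recipe": "coincidence",
  "seed": 1,
  "simulation": {
    "species": [{"n_green": 150, "n_red": 50, "diameter_nm": 60, "n_particles": 13}],
    "confocal": {},
    "sim": {"duration_s": 20, "fine_bin_s": 1e-4}
  },
  "analysis": {"leakage": 0.1, "class_low": 0.25, "class_high": 0.75},
  "output": {"dir": "out_caveola"}
}
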