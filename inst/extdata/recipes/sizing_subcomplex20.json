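{
  "recipe": "sizing",
  "seed": 1,
  "simulation": {
    "species": [{"n_green": 9, "n_red": 0, "diameter_nm": 20, "n_particles": 13}],
    "confocal": {},
    "sim": {"duration_s": 20, "fine_bin_s": 1e-6},
    "reference": {"species": {"n_green": 1, "diameter_nm": 5, "n_particles": 13},
                  "sim": {"duration_s": 20, "fine_bin_s": 1e-6}}
  },
  "analysis": {"window_s": 1, "max_bursts": 80},
  "output": {"dir": "out_sizing20"}
}
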