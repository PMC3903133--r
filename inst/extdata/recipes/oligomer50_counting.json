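{
  "recipe": "counting",
  "seed": 1,
  "simulation": {
    "species": [{"n_green": 50, "n_red": 0, "diameter_nm": 5, "n_particles": 13}],
    "confocal": {},
    "sim": {"duration_s": 40, "fine_bin_s": 1e-4},
    "reference": {"species": {"n_green": 1, "diameter_nm": 5, "n_particles": 13},
                  "sim": {"duration_s": 150, "fine_bin_s": 1e-4}}
  },
  "analysis": {"threshold_photons": 20, "statistic": "peak"},
  "output": {"dir": "out_oligomer50"}
}
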