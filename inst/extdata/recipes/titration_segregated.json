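{
  "recipe": "coincidence",
  "seed": 1,
  "simulation": {
    "mixture": {"n_total_subunits": 50, "green_fraction": 0.5, "mode": "segregated",
                "n_particles": 13, "diameter_nm": 5},
    "confocal": {},
    "sim": {"duration_s": 10, "fine_bin_s": 1e-4}
  },
  "analysis": {"ratio_list": [0, 0.111, 0.222, 0.333, 0.444, 0.556, 0.667, 0.778, 0.889, 1],
               "histogram_bins": 25, "leakage": 0.1},
  "output": {"dir": "out_titration_segregated"}
}
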