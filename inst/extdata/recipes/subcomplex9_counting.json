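{
  "recipe": "counting",
  "seed": 1,
  "simulation": {
    "mixture": {"n_total_subunits": 9, "green_fraction": 0.5, "mode": "mixing",
                "n_particles": 13, "diameter_nm": 5},
    "confocal": {},
    "sim": {"duration_s": 60, "fine_bin_s": 1e-4},
    "reference": {"species": {"n_green": 1, "diameter_nm": 5, "n_particles": 13},
                  "sim": {"duration_s": 150, "fine_bin_s": 1e-4}}
  },
  "analysis": {"threshold_photons": 20, "statistic": "peak",
               "channel": "total_corrected", "leakage": 0.1},
  "output": {"dir": "out_subcomplex9"}
}
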