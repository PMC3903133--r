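# Shared simulation fixtures, built once per test run and cached, so the
# expensive traces (monomer calibration, fine-binned sizing runs) are reused
# across test files.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# coarse (counting-resolution) trace: 100 us bins
coarse_trace <- function(n_green, duration_s, seed, diameter_nm = 5,
                         n_red = 0, species = NULL) {
  simulate_trace(species %||% species_spec(n_green, n_red, diameter_nm, 13),
                 confocal_model(),
                 sim_config(duration_s = duration_s, fine_bin_s = 1e-4,
                            seed = seed))
}

coarse_bursts <- function(...) detect_bursts(coarse_trace(...), 20)

# fine (sizing-resolution) trace: 1 us bins
fine_trace <- function(n_green, duration_s, seed, diameter_nm) {
  simulate_trace(species_spec(n_green, 0, diameter_nm, 13),
                 confocal_model(),
                 sim_config(duration_s = duration_s, fine_bin_s = 1e-6,
                            seed = seed))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# long monomer calibration run shared by counting tests
monomer_bursts_150s <- function() fixture("mono150", coarse_bursts(1, 150, 101))

monomer_reference <- function() fixture("mono_ref", {
  suppressWarnings(calibrate_monomer(monomer_bursts_150s()))
})

# synthetic burst table built directly from channel count vectors
burst_table_from_counts <- function(green, red, bin_width_s = 1e-4) {
  detect_bursts(photon_trace(green, red, bin_width_s), 1)
}
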