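# smburst

Two-colour single-molecule fluorescence burst analysis for protein-complex
stoichiometry, with a Brownian-dynamics photon-trace simulator and spatial
co-clustering statistics.

## Who this is for

Single-molecule spectroscopists who measure dilute (~100 pM) solutions of
GFP/Cherry-tagged protein complexes diffusing through a two-laser confocal
volume, and who want the full burst-analysis chain — detection,
coincidence, subunit counting, per-burst FCS sizing — as tested, scriptable
code rather than instrument-vendor black boxes.  Because such studies
rarely deposit raw photon streams, the package ships a ground-truth-known
generator so every estimator can be checked end to end on synthetic data
with the statistical structure of the real experiment.

## The analysis in brief

A dual-channel photon trace \(I_G(t), I_R(t)\) binned at 100 µs is
thresholded at 20 photons (channels summed); consecutive hot bins are
stitched into bursts.  Per burst:

* **Coincidence** — corrected red \(R^* = \max(0, R - \lambda G)\) with
  crosstalk \(\lambda = 0.1\), and \(C = R^*/(R^* + G)\): 0 for
  green-only, 1 for red-only, intermediate for co-diffusing complexes
  (a 3:1 green:red complex scores 0.25).
* **Brightness counting** — the log-scaled burst-size distribution decays
  linearly (first-order escape from the focal volume); extrapolating the
  fitted tail to one expected event gives the characteristic maximal burst
  size \(b_{max}\) (~100 photons for a GFP monomer), and
  \(\hat N = b_{max}^{sample} / b_{max}^{monomer}\) counts subunits.
* **Sizing** — per-burst multi-tau autocorrelation
  \(g(T) = \langle I(t)I(t{+}T)\rangle / \langle I\rangle^2\) in a 1 s
  window around each burst, fitted with the 3D-Gaussian diffusion model
  \(g(T) = B + A(1+T/\tau)^{-1}(1+T/(S^2\tau))^{-1/2}\) (aspect \(S=5\));
  the Stokes–Einstein relation \(D = k_BT/(3\pi\eta d)\) with
  \(\tau_D = w_{xy}^2/4D\) makes apparent diameter linear in residence
  time: \(d = 5\,\mathrm{nm}\times\tau/\tau_{GFP}\).
* **Spatial statistics** — univariate and bivariate Ripley's
  \(\hat K(r)\) with isotropic edge correction and Monte-Carlo envelopes
  (bivariate null: random relabelling) quantify co-clustering vs
  segregation of two immunogold-labelled species on membrane sheets.

## Worked example

Count the subunits of a simulated 50-mer against a monomer calibration:

```r
library(smburst)

cm  <- confocal_model()                      # 0.2/1.0 um waists, 250 kHz, 10% leakage
mono <- detect_bursts(simulate_trace(
  species_spec(n_green = 1, diameter_nm = 5),  cm,
  sim_config(duration_s = 150, fine_bin_s = 1e-4, seed = 101)), 20)
ref  <- calibrate_monomer(mono)
ref
#> <calibration_reference> monomer b_max 96.9 photons (peak 41.9); tau unset; d 5 nm

b50 <- detect_bursts(simulate_trace(
  species_spec(n_green = 50, diameter_nm = 5), cm,
  sim_config(duration_s = 40,  fine_bin_s = 1e-4, seed = 150)), 20)
estimate_stoichiometry(b50, ref)
#> <stoichiometry_estimate> N = 53.6 (95% CI 50.3-63.7) from 5404 bursts
```

The monomer's stitched-burst envelope extrapolates to ≈100 photons (the
calibration anchor), and the 50-mer is counted at N ≈ 50: `n_hat` is the
ratio of the two characteristic per-bin peak brightnesses.  A two-colour
burst with 300 green and 130 raw red photons gives
`coincidence_ratio(data.frame(photons_green = 300, photons_red_raw = 130), 0.1)`
→ `ratio = 0.25`, the 3:1 stoichiometry signature.

Figure-level recipes (counting, coincidence titrations, sizing, Ripley's
K) are packaged as JSON configs:

```r
run_pipeline(system.file("extdata", "recipes", "oligomer50_counting.json",
                         package = "smburst"), out_dir = "out")
```

or from the shell via the CLI wrapper
(`inst/cli/smburst run --config cfg.json --seed 1 --out out`), with
subcommands `simulate`, `detect`, `coincide`, `count`, `size`, `ripley`,
`report`.

## Layout

* `R/`, `src/` — implementation (R with two small Rcpp kernels: the
  Brownian photon-trace generator and the multi-tau correlator).
* `tests/testthat/` — unit, property and acceptance tests; all fixtures
  are generated in code.
* `vignettes/smburst-methods.Rmd` — models, estimator choices, numerical
  policy and known limitations.
* `inst/extdata/recipes/` — example experiment configs.
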