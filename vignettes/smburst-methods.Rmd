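---
title: "smburst: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{smburst: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`smburst` analyses two-colour single-molecule fluorescence measurements of
freely diffusing protein complexes — the kind of experiment in which a
dilute (~100 pM) solution of GFP- and Cherry-tagged proteins crosses a
confocal detection volume, and each transit produces a burst of photons on
two single-photon counting channels.  From those bursts the pipeline
extracts three independent observables per complex: two-colour
**coincidence** (do the tags co-diffuse?), **brightness** (how many tagged
subunits?), and **residence time** (how large is the complex?).  A
bivariate **Ripley's K** module covers the complementary spatial question
for immunogold-labelled membrane sheets.  Because such measurements rarely
come with deposited raw data, the package includes a Brownian-dynamics
photon-trace generator so that every estimator can be validated against
known ground truth.

# The synthetic measurement

## Photon-trace model

Each particle of a `species_spec` carries `n_green` and `n_red`
fluorophores (thinned by `maturation_fraction`, since cell-free expression
leaves part of a fluorophore population unfolded) and diffuses with the
Stokes–Einstein coefficient for its hydrodynamic diameter,
\(D = k_B T / (3\pi\eta d)\).  Positions evolve as independent Gaussian
random walks (per-axis step s.d. \(\sqrt{2D\,\Delta t}\)) in a cubic box
with periodic re-entry, which keeps the concentration constant without
reflective-wall artefacts.  The detection profile is the standard 3D
Gaussian, \( \mathrm{PSF}(\mathbf r) = \exp(-2(x^2{+}y^2)/w_{xy}^2 -
2z^2/w_z^2) \).  Per integration bin, each channel's Poisson mean is
background plus the brightness-weighted sum of PSF values over particles;
the red channel additionally receives a fraction \(\lambda\) (default
10 %) of the green *signal* mean — additive, one-sided crosstalk that does
not deplete the green channel, mirroring the one-sided correction formula
used downstream.  Counts are independent Poisson draws; a fixed seed gives
a bit-identical trace.

## Defaults and where they come from

Instrument parameters of this kind of confocal setup are rarely printed,
so the defaults are reverse-engineered from two calibration anchors that
*are* standard: a GFP-like monomer (5 nm barrel) should show a residence
time near 100 µs, and its maximal stitched burst should approach 100
photons at the 20-photon detection threshold.

* `waist_xy_um = 0.2`, `waist_z_um = 1.0` (aspect 5), 298 K, 0.89 mPa·s:
  a 5 nm sphere then has \(D \approx 98\,\mu m^2/s\) and
  \(\tau_D = w_{xy}^2/4D \approx 102\,\mu s\).
* `brightness_per_fluor_khz = 250`: fixed once, by simulation, so that the
  monomer's stitched-burst envelope extrapolates to ≈100 photons (measured
  96–110 across seeds).  It is a configuration value, not a constant in
  code.
* Red per-fluorophore brightness defaults to the green value — the
  synthetic analogue of adjusting laser power until both monomers show the
  same burst profile, which is what makes two-channel photon counts
  directly comparable.
* `n_particles = 13` in a (6 µm)³ box corresponds to ≈100 pM.
* Backgrounds of 1 kHz per channel are typical for cleaned-up extracts and
  are negligible at the 20-photon threshold (0.1 counts per 100 µs bin).
* Fine bin width: 1 µs for sizing runs (the instrument's 100 ns is
  supported but oversampled for τ ≥ 100 µs), 100 µs for counting-only
  runs.

What the generator deliberately does **not** model: photobleaching,
blinking, triplet states, detector dead time and afterpulsing.  A green
test therefore establishes correctness of the estimators on ideal
photon statistics, not robustness to those artefacts.

# Burst detection

The trace (both channels summed, by convention — the threshold applies to
"the fluorescence") is binned at 100 µs; a bin at or above 20 photons is
considered occupied, and runs of consecutive occupied bins are stitched
into one burst.  Spans are 0-based half-open; stitching bridges no gaps by
default (`max_gap = 0`).  One documented source quirk: the narrative text
of the underlying protocol says "100 ms" in one place while its methods
say 100 µs twice; 100 µs is the only reading compatible with millisecond
transits, and is the default here.

# Coincidence

For each burst, corrected red \(R^* = \max(0, R_{raw} - \lambda G)\) and
\(C = R^*/(R^* + G)\).  The denominator uses the *corrected* red so that a
true 3:1 green:red burst scores exactly 0.25 (a raw-denominator variant
exists behind a flag).  Negative corrected intensities are clipped to zero
rather than dropping the burst — clipping keeps C in [0, 1] and keeps
event counts conserved; bursts that are empty after correction are flagged
`undefined`, never silently removed.  Classification bounds default to
0.25/0.75.  Titration stacks rebuild the co-expression experiment: a
species factory maps each green expression fraction to a mixture model
(`mixing`, `segregated`, or `capped` incorporation) and one histogram per
ratio is collected.

# Brightness and subunit counting

The burst-size distribution of a diffusing emitter decays exponentially
(escape from the focal volume is a first-order process), so its log-scaled
histogram is linear and can be extrapolated to the size at which one event
is expected among `n_events` — the characteristic maximal burst size
`b_max`.  Two implementation choices deserve explanation:

* **Survival-curve fit.**  The least-squares line is fitted to
  \(\log_{10}\) of the empirical survival count (events ≥ s) over the top
  15 % of sizes (down to 2 surviving events) rather than to raw histogram
  bins.  An exponential tail has the same slope either way, but sparse
  histogram tails — isolated 1-count bins separated by empty bins that a
  log-fit must discard — otherwise flatten the fitted slope and inflate
  the extrapolation by tens of percent.  The binned log-frequency view is
  still computed for plotting and for the curvature warning.
* **Peak statistic for counting.**  `burst_size_profile` defaults to the
  stitched **total** photon count, which is the quantity whose monomer
  envelope sits at ≈100 photons.  Counting operations
  (`estimate_stoichiometry`, `brightness_ratio`) default to the per-bin
  **peak** count instead.  The reason is physical, and was measured, not
  assumed: with a fixed 20-photon threshold, the stitched span of a dim
  monomer transit excludes its sub-threshold wings, while an N-mer's span
  (threshold crossed far out in the PSF skirt) includes nearly the whole
  transit.  Total-photon ratios therefore overestimate N by ~50 % at
  N = 50.  The per-bin peak is proportional to instantaneous emission rate
  — the trajectory ensemble is identical across species of equal size, and
  every count scales with N — and recovers N = 50 within ±3 across seeds.
  Residual small-N bias (~−10 % at N = 9) comes from photon statistics:
  the monomer envelope is broadened upward by Poisson noise (relative
  width \(1/\sqrt{\langle k\rangle}\) is large at ~25 counts), bright
  species negligibly so.
* **Uncertainty.**  The "±" interval is a 200-resample bootstrap over
  bursts, resampling the calibration bursts as well (the reference is an
  estimate, not a constant), with the *basic* (pivotal) interval rather
  than the percentile interval — the envelope extrapolation is nonlinear
  enough that its bootstrap distribution is visibly shifted, and the
  pivotal interval corrects that first-order bias.  Coverage was checked
  at N = 9 (10/10 seeded repeats).

Counting compares a sample against a monomer reference measured under the
same confocal settings **and the same diffusion conditions**; brightness
comparisons between species of different physical size conflate copy
number with residence time unless the peak statistic is used.

# Per-burst FCS sizing

For each burst a window of 1 s on both sides of the 1 µs trace is
autocorrelated on a multi-tau grid (8 points per octave, lag 0 never
reported, so shot noise does not enter).  Two numerical choices were
driven by measurement on ground-truth data rather than taken on faith:

* **Normalization.**  \(\langle I(t)I(t{+}T)\rangle\) is divided by the
  squared *whole-trace* mean, not the window's own means.  A window
  centred on a detected burst has its mean inflated by that burst, and
  the windowed means are correlated with the lagged products; both
  effects tilt the curve.  The whole-trace mean is stable, leaving only a
  constant per-window offset.
* **Free baseline.**  The fit model is the standard 3D Gaussian-volume
  single-component decay
  \[ g(T) = B + A\,(1 + T/\tau)^{-1} (1 + T/(S^2\tau))^{-1/2} \]
  with aspect fixed at \(S = 5\), \(A, \tau\) free (Nelder–Mead on
  log-parameters, initial τ from the half-decay lag), and baseline \(B\)
  free to absorb the local/global mean ratio; for a stationary segment it
  fits \(B \approx 1\).

No triplet term is included — the measurement this emulates avoided the
red channel for FCS precisely because of triplet contamination, and the
generator does not produce triplets.  Non-decaying curves are rejected,
counted and reported, never silently dropped.

The window length is not a free knob.  Shortening it below the default
1 s biases τ low for slow species (measured −30 % at 0.5 s for a 1.2 ms
decay): the window's photon-pair weight concentrates on its central
transit, and the curve then reflects that single transit's dwell rather
than the local ensemble.  Conversely, because consecutive bursts sit much
closer together than one window, neighbouring windows overlap almost
completely and per-burst estimates are strongly correlated — the
effective number of independent residence-time estimates is roughly the
trace length divided by the window span, regardless of how many bursts
are fitted.  Sizing runs therefore use long traces with bursts thinned
evenly across them, and the tests assert medians at tolerances that
respect this effective sample size.

Diameter conversion is linear calibration against the monomer:
\(d = d_{ref}\,\tau/\tau_{ref}\) with \(d_{ref} = 5\) nm, valid because
\(\tau_D = w^2/4D\) and \(D \propto 1/d\).  Sizes below the reference are
reported as-is.  The sphere assumption is an interpretive simplification
and is recorded as such in output metadata.  Note one deliberate
non-reconciliation: a 60 nm sphere is 12× the 5 nm reference, while the
emulated study rounds the same comparison to "10 times slower"; the
package reports what its inputs imply and does not massage either number.

# Ripley's K

Univariate \(\hat K(r) = (|A|/n^2)\sum_{i\neq j} w_{ij}^{-1}
\mathbf 1[d_{ij}\le r]\) and bivariate
\(\hat K_{ab}(r) = (|A|/(n_a n_b))\sum_i\sum_j \cdots\), with Ripley's
isotropic edge correction in a rectangular window (Goreaud–Pélissier arc
formula, valid for \(r \le \min(W,H)/4\), which is also the enforced
radius cap); translation correction and no correction are available, the
latter doubling as the brute-force oracle hook.  The bivariate null is
**random relabelling** of the pooled points, not independent CSR: membrane
proteins cluster on caveolae no matter what, and the biological question
is whether the two species associate *given* that clustering.  Envelopes
are pointwise quantile bands from seeded simulations (default 199 for
95 %).  The co-clustering verdict follows the smallest escaping radius:
segregation inside a parent disk necessarily pushes cross-species pairs
just beyond the disk diameter, so large-radius excursions above the null
are a geometric echo, not association.

# Numerical and degenerate-input policy

* Empty traces, sub-threshold traces and empty species lists return empty,
  typed results; undefined coincidence bursts are flagged.
* Burst-size profiles require ≥ 100 bursts and at least 3 distinct tail
  sizes; identical sizes and non-decaying tails are hard errors.
* Residence fits require ≥ 10 finite lags and a decaying curve; failures
  are skipped and counted per run.
* All randomness flows from explicit integer seeds; repeated runs are
  bit-identical, which the tests assert.

# Known limitations

* The counting statistic's small-N Poisson bias (above) is inherent to
  envelope extrapolation on few-photon peaks; at N ≤ 9 expect ~10 %
  underestimation in this stated world.
* Double occupancy of the detection region (~10 % of burst time at 100 pM
  for bright species) inflates the extreme brightness tail; the envelope's
  extrapolation-to-1-event is moderately robust to it, the literal maximum
  is not.
* No inhomogeneous-K, pair-correlation function, or 3D K; membrane sheets
  are treated as planar and homogeneous.
* The CLI's config format is JSON (schema-validated, unknown keys
  rejected); YAML was not adopted because the deployment environment
  provides no R YAML parser.
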