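#' Describe a simulated particle species
#'
#' Ground-truth description of one diffusing population: how many green and
#' red fluorophores each particle carries, its hydrodynamic diameter, how
#' many particles populate the simulation box (the proxy for a ~100 pM
#' working concentration) and which fraction of fluorophores is emissive
#' (cell-free expression leaves some fluorophores unfolded).
#'
#' @param n_green,n_red Integer fluorophore counts per particle (>= 0, at
#'   least one in total).
#' @param diameter_nm Hydrodynamic diameter in nm (> 0).
#' @param n_particles Number of particles of this species in the box.
#' @param maturation_fraction Probability that a given fluorophore is
#'   emissive, in [0, 1].
#' @return A \code{species_spec} object.
#' @examples
#' species_spec(n_green = 1, diameter_nm = 5)          # a GFP-like monomer
#' species_spec(n_green = 50, diameter_nm = 60)        # a 50-mer assembly
#' @export
species_spec <- function(n_green = 1, n_red = 0, diameter_nm = 5,
                         n_particles = 13, maturation_fraction = 1) {
  stopifnot(n_green >= 0, n_red >= 0, n_green + n_red >= 1,
            diameter_nm > 0, n_particles >= 0,
            maturation_fraction >= 0, maturation_fraction <= 1)
  structure(list(n_green = as.integer(round(n_green)),
                 n_red = as.integer(round(n_red)),
                 diameter_nm = diameter_nm,
                 n_particles = as.integer(round(n_particles)),
                 maturation_fraction = maturation_fraction),
            class = "species_spec")
}

#' @export
print.species_spec <- function(x, ...) {
  cat(sprintf("<species_spec> %d green + %d red fluorophores, d = %g nm, %d particles (maturation %.2f)\n",
              x$n_green, x$n_red, x$diameter_nm, x$n_particles,
              x$maturation_fraction))
  invisible(x)
}

#' Describe the confocal detection volume and channel response
#'
#' The detection profile is a 3D Gaussian with lateral and axial 1/e^2
#' waists.  Brightness is the peak detected count rate of one emissive
#' fluorophore at the volume centre.  The default brightness is chosen so
#' that a single green fluorophore under default settings yields a maximal
#' stitched burst of about 100 photons, the monomer calibration anchor;
#' red brightness defaults to the green value, mimicking an excitation
#' power adjusted for matched burst profiles.  Crosstalk duplicates a
#' fraction \code{leakage} of green signal photons into the red channel
#' without depleting the green channel.
#'
#' @param waist_xy_um,waist_z_um Lateral and axial 1/e^2 radii in um
#'   (axial >= lateral > 0).  The defaults (0.2, 1.0) are reverse-engineered
#'   so that a 5 nm sphere at 298 K in water has a ~100 us residence time.
#' @param brightness_per_fluor_khz Peak per-fluorophore detected rate (kHz).
#' @param brightness_red_khz Red-channel per-fluorophore rate; defaults to
#'   the green value.
#' @param leakage Green-to-red crosstalk fraction in [0, 1).
#' @param background_khz_green,background_khz_red Channel backgrounds (kHz).
#' @param temperature_K,viscosity_mPas Bath conditions used for
#'   Stokes-Einstein diffusion.
#' @return A \code{confocal_model} object.
#' @export
confocal_model <- function(waist_xy_um = 0.2, waist_z_um = 1.0,
                           brightness_per_fluor_khz = 250,
                           brightness_red_khz = brightness_per_fluor_khz,
                           leakage = 0.1,
                           background_khz_green = 1, background_khz_red = 1,
                           temperature_K = 298, viscosity_mPas = 0.89) {
  stopifnot(waist_xy_um > 0, waist_z_um >= waist_xy_um,
            leakage >= 0, leakage < 1,
            brightness_per_fluor_khz >= 0, brightness_red_khz >= 0,
            background_khz_green >= 0, background_khz_red >= 0,
            temperature_K > 0, viscosity_mPas > 0)
  structure(list(waist_xy_um = waist_xy_um, waist_z_um = waist_z_um,
                 brightness_per_fluor_khz = brightness_per_fluor_khz,
                 brightness_red_khz = brightness_red_khz,
                 leakage = leakage,
                 background_khz_green = background_khz_green,
                 background_khz_red = background_khz_red,
                 temperature_K = temperature_K,
                 viscosity_mPas = viscosity_mPas),
            class = "confocal_model")
}

#' @export
print.confocal_model <- function(x, ...) {
  cat(sprintf("<confocal_model> waists %g x %g um, %g kHz/fluorophore, leakage %.0f%%, bg %g/%g kHz\n",
              x$waist_xy_um, x$waist_z_um, x$brightness_per_fluor_khz,
              100 * x$leakage, x$background_khz_green, x$background_khz_red))
  invisible(x)
}

#' Configure a Brownian photon-trace simulation
#'
#' @param duration_s Trace length in seconds.
#' @param fine_bin_s Integration/output resolution of the raw trace in
#'   seconds.  1 us is the sizing default (the instrument's 100 ns is
#'   supported but unnecessary at desk scale); counting-only runs can use
#'   100 us directly.
#' @param box_halfwidth_um Half-width of the cubic simulation region with
#'   periodic re-entry; must be at least 3x the paired confocal model's
#'   axial waist.
#' @param seed Integer random seed recorded into the trace metadata.
#' @return A \code{sim_config} object.
#' @export
sim_config <- function(duration_s = 10, fine_bin_s = 1e-4,
                       box_halfwidth_um = 3, seed = 1L) {
  stopifnot(fine_bin_s > 0, duration_s >= fine_bin_s, box_halfwidth_um > 0)
  structure(list(duration_s = duration_s, fine_bin_s = fine_bin_s,
                 box_halfwidth_um = box_halfwidth_um,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Configure a two-species gold-particle point-pattern simulation
#'
#' Emulates immunogold labelling geometries on membrane lawns: complete
#' spatial randomness (\code{csr}), both species clustered around shared
#' caveola centres (\code{clustered_coassembled}), or clustered around
#' shared centres but confined to disjoint angular sectors of each parent
#' disk, mimicking segregated striations (\code{clustered_segregated}).
#'
#' @param model_kind One of \code{"csr"}, \code{"clustered_coassembled"},
#'   \code{"clustered_segregated"}.
#' @param window_nm Numeric length-2 rectangle (width, height) in nm.
#' @param n_parents Number of caveola centres.
#' @param parent_radius_nm Offspring scatter radius (caveola scale, ~30 nm).
#' @param n_offspring_green,n_offspring_red Mean gold particles per parent
#'   and species.
#' @param seed Integer random seed.
#' @return A \code{point_pattern_model} object.
#' @export
point_pattern_model <- function(model_kind = c("csr", "clustered_coassembled",
                                               "clustered_segregated"),
                                window_nm = c(1000, 1000),
                                n_parents = 20, parent_radius_nm = 30,
                                n_offspring_green = 10, n_offspring_red = 10,
                                seed = 1L) {
  model_kind <- match.arg(model_kind)
  stopifnot(length(window_nm) == 2, all(window_nm > 0),
            n_parents >= 0, n_offspring_green >= 0, n_offspring_red >= 0)
  if (model_kind != "csr" && parent_radius_nm <= 0) {
    stop("parent_radius_nm must be positive for clustered models")
  }
  structure(list(model_kind = model_kind, window_nm = as.numeric(window_nm),
                 n_parents = as.integer(n_parents),
                 parent_radius_nm = parent_radius_nm,
                 n_offspring_green = n_offspring_green,
                 n_offspring_red = n_offspring_red,
                 seed = as.integer(seed)),
            class = "point_pattern_model")
}
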