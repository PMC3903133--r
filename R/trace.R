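#' Construct a dual-channel photon trace
#'
#' @param green,red Non-negative integer count vectors of equal length.
#' @param bin_width_s Seconds per bin (> 0).
#' @param meta Optional provenance list (seed, config hash, ...).
#' @return A \code{photon_trace} object.
#' @export
photon_trace <- function(green, red, bin_width_s, meta = list()) {
  green <- as.integer(green); red <- as.integer(red)
  stopifnot(length(green) == length(red), bin_width_s > 0,
            all(green >= 0), all(red >= 0))
  structure(list(green = green, red = red, bin_width_s = bin_width_s,
                 meta = meta),
            class = "photon_trace")
}

#' @export
print.photon_trace <- function(x, ...) {
  cat(sprintf("<photon_trace> %d bins x %g s = %.3g s; %d green / %d red photons\n",
              length(x$green), x$bin_width_s,
              length(x$green) * x$bin_width_s,
              sum(x$green), sum(x$red)))
  invisible(x)
}

#' @export
length.photon_trace <- function(x) length(x$green)

#' Simulate a dual-channel photon trace of diffusing labelled particles
#'
#' Brownian-dynamics emulation of a two-colour confocal single-molecule
#' measurement.  Every particle of every species performs an independent
#' Gaussian random walk (per-axis step s.d. \eqn{\sqrt{2 D \Delta t}}, D from
#' Stokes-Einstein at the species diameter) in a cubic box with periodic
#' re-entry.  Per fine bin, each channel's Poisson mean sums the per-particle
#' emissive fluorophore counts weighted by a 3D Gaussian detection profile,
#' plus channel background; the red channel additionally receives
#' \code{leakage} times the green signal mean (additive crosstalk, green
#' channel not depleted).  Counts are independent Poisson draws; an
#' identical seed yields a bit-identical trace.
#'
#' @param species A \code{\link{species_spec}} or list of them.
#' @param confocal A \code{\link{confocal_model}}.
#' @param config A \code{\link{sim_config}}; its seed drives all randomness.
#' @param init_positions Optional matrix (total particles x 3, um) of start
#'   positions; default uniform in the box.
#' @param immobile If TRUE, particles do not move (diagnostic use: a pinned
#'   emitter produces a pure Poisson stream at fixed mean).
#' @return A \code{\link{photon_trace}} with full provenance in \code{$meta}.
#' @export
simulate_trace <- function(species, confocal = confocal_model(),
                           config = sim_config(),
                           init_positions = NULL, immobile = FALSE) {
  if (inherits(species, "species_spec")) species <- list(species)
  stopifnot(all(vapply(species, inherits, TRUE, "species_spec")),
            inherits(confocal, "confocal_model"),
            inherits(config, "sim_config"))
  if (config$box_halfwidth_um < 3 * confocal$waist_z_um) {
    stop("simulation box too small: box_halfwidth_um must be >= 3 x waist_z_um")
  }

  set.seed(config$seed)
  ng <- nr <- dd <- numeric(0)
  for (sp in species) {
    if (sp$n_particles == 0) next
    g <- if (sp$maturation_fraction < 1) {
      stats::rbinom(sp$n_particles, sp$n_green, sp$maturation_fraction)
    } else rep(sp$n_green, sp$n_particles)
    r <- if (sp$maturation_fraction < 1) {
      stats::rbinom(sp$n_particles, sp$n_red, sp$maturation_fraction)
    } else rep(sp$n_red, sp$n_particles)
    ng <- c(ng, g); nr <- c(nr, r)
    dd <- c(dd, rep(sp$diameter_nm, sp$n_particles))
  }
  d_um2s <- if (length(dd)) {
    stokes_einstein_diffusion(dd, confocal$temperature_K,
                              confocal$viscosity_mPas)
  } else numeric(0)
  if (immobile) d_um2s <- rep(0, length(d_um2s))

  n_bins <- floor(config$duration_s / config$fine_bin_s)
  init <- if (is.null(init_positions)) {
    matrix(numeric(0), nrow = 0, ncol = 3)
  } else {
    stopifnot(nrow(init_positions) == length(ng), ncol(init_positions) == 3)
    init_positions
  }

  res <- sim_trace_cpp(n_bins, config$fine_bin_s,
                       as.numeric(ng), as.numeric(nr), as.numeric(d_um2s),
                       confocal$waist_xy_um, confocal$waist_z_um,
                       confocal$brightness_per_fluor_khz * 1000,
                       confocal$brightness_red_khz * 1000,
                       confocal$leakage,
                       confocal$background_khz_green * 1000,
                       confocal$background_khz_red * 1000,
                       config$box_halfwidth_um, init)

  meta <- list(seed = config$seed, config = config, confocal = confocal,
               species = species,
               config_hash = config_hash(list(config, confocal, species)))
  photon_trace(res$green, res$red, config$fine_bin_s, meta)
}

#' Re-bin a photon trace to a coarser resolution
#'
#' Sums counts over non-overlapping windows of \code{factor} bins; a
#' trailing remainder shorter than \code{factor} is dropped.  Total photons
#' are conserved up to that remainder.
#'
#' @param trace A \code{\link{photon_trace}}.
#' @param factor Positive integer coarsening factor.
#' @return A \code{\link{photon_trace}} with \code{bin_width_s * factor}.
#' @export
rebin_trace <- function(trace, factor) {
  stopifnot(inherits(trace, "photon_trace"))
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1) stop("rebin factor must be a positive integer")
  if (factor == 1) return(trace)
  n <- (length(trace$green) %/% factor) * factor
  if (n == 0) stop("trace shorter than one rebinned bin")
  idx <- rep(seq_len(n %/% factor), each = factor)
  photon_trace(rowsum(trace$green[seq_len(n)], idx),
               rowsum(trace$red[seq_len(n)], idx),
               trace$bin_width_s * factor, trace$meta)
}

#' Write / read a photon trace as CSV plus a JSON sidecar
#'
#' The CSV holds \code{bin_index} (0-based), \code{green_counts},
#' \code{red_counts}; the sidecar (same path with \code{.json} appended)
#' records the bin width and the full provenance metadata.
#'
#' @param trace A \code{\link{photon_trace}}.
#' @param path Output CSV path.
#' @return \code{write_trace}: the path, invisibly. \code{read_trace}: a
#'   \code{\link{photon_trace}}.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "photon_trace"))
  utils::write.csv(data.frame(bin_index = seq_along(trace$green) - 1L,
                              green_counts = trace$green,
                              red_counts = trace$red),
                   path, row.names = FALSE)
  side <- list(bin_width_s = trace$bin_width_s,
               n_bins = length(trace$green),
               meta = serializable_meta(trace$meta))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- utils::read.csv(path)
  side_path <- paste0(path, ".json")
  if (!file.exists(side_path)) {
    stop("missing JSON sidecar for trace: ", side_path)
  }
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  photon_trace(df$green_counts, df$red_counts, side$bin_width_s,
               as.list(side$meta))
}

# strip closures/classes so metadata serializes cleanly
serializable_meta <- function(meta) {
  rapply(meta, f = function(x) x, how = "list")
}
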