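#' Read and validate an experiment configuration
#'
#' Configurations are JSON with blocks \code{recipe} (one of
#' \code{"counting"}, \code{"coincidence"}, \code{"sizing"},
#' \code{"ripley"}), \code{seed}, \code{simulation} (species or mixture,
#' confocal and sim settings, optional monomer \code{reference} block),
#' \code{analysis}, \code{spatial} and \code{output}.  Unknown keys are
#' rejected rather than ignored, so typos cannot silently change an
#' experiment.  Packaged example recipes live under
#' \code{system.file("extdata", "recipes", package = "smburst")}.
#'
#' @param path Path to a JSON config file.
#' @return A validated config list with class \code{experiment_config}.
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  validate_config(cfg)
}

#' @rdname read_config
#' @param cfg A config list built in code.
#' @export
validate_config <- function(cfg) {
  check_keys <- function(x, allowed, where) {
    bad <- setdiff(names(x), allowed)
    if (length(bad)) stop(sprintf("unknown %s key(s): %s", where,
                                  paste(bad, collapse = ", ")))
  }
  check_keys(cfg, c("recipe", "seed", "simulation", "analysis", "spatial",
                    "output"), "config")
  if (is.null(cfg$recipe) ||
      !cfg$recipe %in% c("counting", "coincidence", "sizing", "ripley")) {
    stop("config must name a recipe: counting, coincidence, sizing or ripley")
  }
  if (is.null(cfg$seed)) cfg$seed <- 1L
  check_keys(cfg$simulation, c("species", "mixture", "confocal", "sim",
                               "reference"), "simulation")
  check_keys(cfg$analysis, c("threshold_photons", "leakage", "class_low",
                             "class_high", "histogram_bins", "window_s",
                             "confocal_aspect", "counting_bin_s",
                             "max_bursts", "ratio_list", "channel",
                             "statistic", "reference_diameter_nm"),
             "analysis")
  check_keys(cfg$spatial, c("model", "radii_nm", "n_sim", "confidence",
                            "edge_correction"), "spatial")
  check_keys(cfg$output, c("dir"), "output")
  structure(cfg, class = c("experiment_config", "list"))
}

cfg_confocal <- function(cfg) do.call(confocal_model,
                                      as.list(cfg$simulation$confocal))

cfg_sim <- function(cfg, seed) {
  args <- as.list(cfg$simulation$sim)
  args$seed <- seed
  do.call(sim_config, args)
}

cfg_species <- function(block) {
  if (!is.null(block$mixture)) {
    return(do.call(make_coassembly_mixture, as.list(block$mixture)))
  }
  sp <- block$species
  if (is.null(sp)) stop("simulation block needs 'species' or 'mixture'")
  if (!is.null(names(sp))) sp <- list(sp)   # single species given flat
  lapply(sp, function(s) do.call(species_spec, as.list(s)))
}

a_get <- function(cfg, key, default) {
  v <- cfg$analysis[[key]]
  if (is.null(v)) default else v
}

#' Run a figure-level experiment recipe end to end
#'
#' Executes simulate, detect and the recipe's analysis (coincidence,
#' counting, sizing or spatial statistics) from a single config, writing a
#' result bundle (CSV/JSON files plus a \code{manifest.json} stamping the
#' config hash and seed) to the output directory.  Re-running with the same
#' config produces bit-identical results.  Skipped bursts and dropped
#' events are counted in the outputs, never silently discarded.
#'
#' @param config An \code{experiment_config} (see \code{\link{read_config}})
#'   or a path to one.
#' @param out_dir Output directory; overrides the config's
#'   \code{output$dir}.
#' @return Invisibly, a list of in-memory results (also written to disk).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- if (is.character(config)) read_config(config) else
    validate_config(config)
  out <- out_dir %||% cfg$output$dir %||% "."
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(unclass(cfg))
  seed <- as.integer(cfg$seed)

  results <- switch(cfg$recipe,
    coincidence = run_coincidence(cfg, out, seed),
    counting = run_counting(cfg, out, seed),
    sizing = run_sizing(cfg, out, seed),
    ripley = run_ripley(cfg, out, seed))

  jsonlite::write_json(list(recipe = cfg$recipe, seed = seed,
                            config_hash = hash,
                            files = results$files),
                       file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(results, list(config_hash = hash)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

run_coincidence <- function(cfg, out, seed) {
  confocal <- cfg_confocal(cfg)
  leak <- a_get(cfg, "leakage", confocal$leakage)
  thr <- a_get(cfg, "threshold_photons", 20)
  nb <- a_get(cfg, "histogram_bins", 25)
  ratios <- cfg$analysis$ratio_list

  if (!is.null(ratios)) {
    mix <- as.list(cfg$simulation$mixture)
    factory <- function(f) { mix$green_fraction <- f
                             do.call(make_coassembly_mixture, mix) }
    stack <- titration_stack(ratios, factory, confocal, cfg_sim(cfg, seed),
                             thr, leak, nb)
    write_coincidence(stack, file.path(out, "titration.csv"))
    return(list(stack = stack, files = "titration_index.json"))
  }
  trace <- simulate_trace(cfg_species(cfg$simulation), confocal,
                          cfg_sim(cfg, seed))
  bursts <- detect_bursts(trace, thr)
  cc <- classify_bursts(coincidence_ratio(bursts, leak),
                        a_get(cfg, "class_low", 0.25),
                        a_get(cfg, "class_high", 0.75))
  h <- coincidence_histogram(cc, nb)
  write_bursts(bursts, file.path(out, "bursts.csv"))
  write_coincidence(h, file.path(out, "coincidence.csv"))
  list(bursts = bursts, coincidence = cc, histogram = h,
       files = c("bursts.csv", "coincidence.csv"))
}

sim_pair <- function(cfg, seed) {
  confocal <- cfg_confocal(cfg)
  ref_block <- cfg$simulation$reference %||%
    list(species = list(n_green = 1, diameter_nm = 5))
  ref_species <- cfg_species(ref_block)
  ref_simcfg <- if (!is.null(ref_block$sim)) {
    args <- as.list(ref_block$sim); args$seed <- as.integer(derive_seed(seed, 1))
    do.call(sim_config, args)
  } else cfg_sim(cfg, as.integer(derive_seed(seed, 1)))
  list(confocal = confocal,
       reference = simulate_trace(ref_species, confocal, ref_simcfg),
       sample = simulate_trace(cfg_species(cfg$simulation), confocal,
                               cfg_sim(cfg, as.integer(derive_seed(seed, 2)))))
}

run_counting <- function(cfg, out, seed) {
  p <- sim_pair(cfg, seed)
  thr <- a_get(cfg, "threshold_photons", 20)
  chan <- a_get(cfg, "channel", "sum")
  leak <- a_get(cfg, "leakage", p$confocal$leakage)
  cbin <- a_get(cfg, "counting_bin_s", 1e-4)
  to_counting <- function(tr) {
    f <- round(cbin / tr$bin_width_s)
    if (f > 1) rebin_trace(tr, f) else tr
  }
  ref_bursts <- detect_bursts(to_counting(p$reference), thr)
  sam_bursts <- detect_bursts(to_counting(p$sample), thr)
  ref <- calibrate_monomer(ref_bursts, channel = chan)
  est <- estimate_stoichiometry(sam_bursts, ref, channel = chan,
                                leakage = leak,
                                statistic = a_get(cfg, "statistic", "peak"),
                                seed = as.integer(derive_seed(seed, 3)))
  report <- list(n_hat = est$n_hat, ci_low = est$ci_low,
                 ci_high = est$ci_high, n_bursts = est$n_bursts,
                 reference_b_max = est$reference_b_max,
                 reference_b_max_total = ref$monomer_b_max)
  jsonlite::write_json(report, file.path(out, "stoichiometry.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_bursts(sam_bursts, file.path(out, "bursts.csv"))
  list(estimate = est, reference = ref,
       files = c("stoichiometry.json", "bursts.csv"))
}

run_sizing <- function(cfg, out, seed) {
  p <- sim_pair(cfg, seed)
  thr <- a_get(cfg, "threshold_photons", 20)
  win <- a_get(cfg, "window_s", 1)
  aspect <- a_get(cfg, "confocal_aspect",
                  p$confocal$waist_z_um / p$confocal$waist_xy_um)
  maxb <- a_get(cfg, "max_bursts", Inf)
  cbin <- a_get(cfg, "counting_bin_s", 1e-4)
  detect_fine <- function(tr) {
    detect_bursts(rebin_trace(tr, round(cbin / tr$bin_width_s)), thr)
  }
  ref_sizes <- size_bursts(p$reference, detect_fine(p$reference),
                           window_s = win, confocal_aspect = aspect,
                           max_bursts = maxb)
  reference <- set_reference_tau(
    structure(list(monomer_b_max = NA_real_,
                   reference_diameter_nm = a_get(cfg, "reference_diameter_nm", 5),
                   reference_tau_s = NULL),
              class = "calibration_reference"),
    stats::median(ref_sizes$tau_s, na.rm = TRUE))
  sizes <- size_bursts(p$sample, detect_fine(p$sample), reference,
                       window_s = win, confocal_aspect = aspect,
                       max_bursts = maxb)
  utils::write.csv(sizes, file.path(out, "sizes.csv"), row.names = FALSE)
  summary <- list(median_diameter_nm = stats::median(sizes$diameter_nm,
                                                     na.rm = TRUE),
                  reference_tau_s = reference$reference_tau_s,
                  n_fitted = sum(!is.na(sizes$tau_s)),
                  n_skipped = attr(sizes, "n_skipped"))
  jsonlite::write_json(summary, file.path(out, "sizing_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  list(sizes = sizes, reference = reference, summary = summary,
       files = c("sizes.csv", "sizing_summary.json"))
}

run_ripley <- function(cfg, out, seed) {
  model_args <- as.list(cfg$spatial$model)
  model_args$seed <- seed
  model <- do.call(point_pattern_model, model_args)
  pats <- generate_point_pattern(model)
  radii <- cfg$spatial$radii_nm %||% seq(10, 200, by = 10)
  kk <- monte_carlo_envelope(pats$green, pats$red, radii,
                             cfg$spatial$edge_correction %||% "isotropic",
                             cfg$spatial$n_sim %||% 199,
                             cfg$spatial$confidence %||% 0.95,
                             seed = as.integer(derive_seed(seed, 4)))
  write_point_pattern(pats, file.path(out, "pattern.csv"))
  write_kfun(kk, file.path(out, "kfunction.csv"))
  list(patterns = pats, k = kk,
       files = c("pattern.csv", "kfunction.csv"))
}
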