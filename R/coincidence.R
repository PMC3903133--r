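#' Leakage-corrected two-colour coincidence ratio
#'
#' For each burst the red total is corrected for green-to-red crosstalk,
#' \eqn{R^* = \max(0, R_{raw} - \lambda G)}, and the coincidence ratio is
#' \eqn{C = R^* / (R^* + G)}: 0 for a green-only burst, 1 for red-only,
#' intermediate values measure the stoichiometry of a co-diffusing
#' two-colour complex (a true 3:1 green:red burst scores exactly 0.25).
#' The denominator uses the corrected red intensity; set
#' \code{corrected_denominator = FALSE} for the raw-red variant.  Bursts
#' with both channels zero after correction are flagged
#' \code{undefined = TRUE}, not dropped.
#'
#' @param bursts A \code{burst_table} (or data.frame with
#'   \code{photons_green} and \code{photons_red_raw}).
#' @param leakage Crosstalk fraction \eqn{\lambda} in [0, 1); default 0.1.
#' @param corrected_denominator Use corrected red in the denominator
#'   (default TRUE).
#' @return A \code{coincidence_table}: the burst columns plus
#'   \code{photons_red_corrected}, \code{ratio}, \code{undefined} and a
#'   default \code{label} at thresholds 0.25/0.75 (see
#'   \code{\link{classify_bursts}} to relabel).
#' @export
coincidence_ratio <- function(bursts, leakage = 0.1,
                              corrected_denominator = TRUE) {
  if (leakage < 0 || leakage >= 1) stop("leakage must be in [0, 1)")
  g <- bursts$photons_green
  r_raw <- bursts$photons_red_raw
  r_star <- pmax(0, r_raw - leakage * g)
  denom <- if (corrected_denominator) r_star + g else r_raw + g
  undef <- denom == 0
  ratio <- ifelse(undef, NA_real_, r_star / denom)
  out <- cbind(as.data.frame(bursts),
               data.frame(photons_red_corrected = r_star, ratio = ratio,
                          undefined = undef))
  out <- classify_bursts(out, 0.25, 0.75)
  attr(out, "leakage") <- leakage
  class(out) <- c("coincidence_table", "data.frame")
  out
}

#' Classify bursts by coincidence ratio
#'
#' \eqn{C < low} is green-only, \eqn{C > high} red-only, anything between
#' is a coincident two-colour burst.  Defaults 0.25/0.75.
#'
#' @param results A \code{coincidence_table} from
#'   \code{\link{coincidence_ratio}}.
#' @param low,high Classification bounds, \eqn{0 < low < high < 1}.
#' @return The table with a \code{label} factor and attribute
#'   \code{fraction_coincident} (undefined bursts excluded from the
#'   denominator).
#' @export
classify_bursts <- function(results, low = 0.25, high = 0.75) {
  stopifnot(low > 0, high < 1, low < high)
  lab <- ifelse(is.na(results$ratio), NA_character_,
         ifelse(results$ratio < low, "green_only",
         ifelse(results$ratio > high, "red_only", "coincident")))
  results$label <- factor(lab, levels = c("green_only", "coincident",
                                          "red_only"))
  ok <- !is.na(results$label)
  attr(results, "fraction_coincident") <-
    if (any(ok)) mean(results$label[ok] == "coincident") else NA_real_
  attr(results, "class_bounds") <- c(low = low, high = high)
  results
}

#' Histogram of coincidence ratios
#'
#' @param results A \code{coincidence_table}.
#' @param n_bins Number of uniform bins on [0, 1] (>= 10; default 25).
#' @return A \code{coincidence_histogram}: list with \code{bin_edges},
#'   \code{counts}, \code{n_events} (defined-ratio bursts), and metadata
#'   recording dropped-undefined counts and a low-event warning flag when
#'   fewer than 100 events were available.
#' @export
coincidence_histogram <- function(results, n_bins = 25) {
  if (n_bins < 10) stop("n_bins must be >= 10")
  cc <- results$ratio[!is.na(results$ratio)]
  edges <- seq(0, 1, length.out = n_bins + 1)
  # left-closed bins; include.lowest puts C = 1 in the last bin
  counts <- graphics::hist(cc, breaks = edges, plot = FALSE,
                           include.lowest = TRUE, right = FALSE)$counts
  meta <- list(n_undefined = sum(is.na(results$ratio)),
               low_events = length(cc) < 100)
  structure(list(bin_edges = edges, counts = counts, n_events = length(cc),
                 meta = meta),
            class = "coincidence_histogram")
}

#' @export
print.coincidence_histogram <- function(x, ...) {
  cat(sprintf("<coincidence_histogram> %d events in %d bins%s\n",
              x$n_events, length(x$counts),
              if (isTRUE(x$meta$low_events)) " [low-event warning]" else ""))
  invisible(x)
}

#' Titration stack of coincidence histograms
#'
#' Re-creates the expression-ratio titration experiment: for each green
#' fraction in \code{ratio_list} a particle population is built by
#' \code{species_factory}, a trace is simulated, bursts detected and a
#' coincidence histogram computed.  Stacking the histograms over the ratio
#' axis gives the familiar 3D view in which co-assembling subunits show a
#' coincident peak sweeping from 0 to 1 while non-interacting pairs stay
#' bimodal at the edges.
#'
#' @param ratio_list Green fractions in [0, 1] (typically 10 steps 0..1).
#' @param species_factory \code{function(green_fraction)} returning a
#'   species list (see \code{\link{make_coassembly_mixture}}).
#' @param confocal,config Simulation settings; the config seed is offset
#'   per ratio so replicate traces are independent but reproducible.
#' @param threshold_photons,leakage,n_bins Analysis settings.
#' @return A \code{titration_stack}: list of
#'   \code{\link{coincidence_histogram}} objects with the ratios as an
#'   attribute.
#' @export
titration_stack <- function(ratio_list, species_factory,
                            confocal = confocal_model(),
                            config = sim_config(),
                            threshold_photons = 20, leakage = 0.1,
                            n_bins = 25) {
  stopifnot(all(ratio_list >= 0), all(ratio_list <= 1))
  out <- vector("list", length(ratio_list))
  for (i in seq_along(ratio_list)) {
    cfg_i <- config
    cfg_i$seed <- as.integer(derive_seed(config$seed, i))
    trace <- simulate_trace(species_factory(ratio_list[i]), confocal, cfg_i)
    bursts <- detect_bursts(trace, threshold_photons)
    out[[i]] <- coincidence_histogram(coincidence_ratio(bursts, leakage),
                                      n_bins)
  }
  structure(out, ratios = ratio_list, class = "titration_stack")
}

#' Export a coincidence histogram (or stack) to CSV
#'
#' One row per bin: \code{bin_left}, \code{bin_right}, \code{count}; a JSON
#' sidecar carries the event counts and warnings.  For a stack, one file
#' per ratio plus an index manifest.
#'
#' @param hist A \code{coincidence_histogram} or \code{titration_stack}.
#' @param path CSV path (for stacks, a stem: files \code{<stem>_<i>.csv}).
#' @export
write_coincidence <- function(hist, path) {
  if (inherits(hist, "titration_stack")) {
    ratios <- attr(hist, "ratios")
    files <- character(length(hist))
    for (i in seq_along(hist)) {
      files[i] <- sprintf("%s_%02d.csv", sub("\\.csv$", "", path), i)
      write_coincidence(hist[[i]], files[i])
    }
    jsonlite::write_json(list(ratios = ratios, files = basename(files)),
                         paste0(sub("\\.csv$", "", path), "_index.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(path))
  }
  n <- length(hist$counts)
  utils::write.csv(data.frame(bin_left = hist$bin_edges[-(n + 1)],
                              bin_right = hist$bin_edges[-1],
                              count = hist$counts),
                   path, row.names = FALSE)
  jsonlite::write_json(c(list(n_events = hist$n_events), hist$meta),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
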