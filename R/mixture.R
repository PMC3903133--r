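#' Build a two-colour co-assembly mixture of species
#'
#' Describes the particle populations produced when green- and red-tagged
#' subunits co-assemble at a given expression ratio.  Three idealised
#' assembly behaviours are supported:
#' \describe{
#'   \item{mixing}{subunits assemble indifferently, so the per-particle
#'     green/red composition is binomial(\code{n_total_subunits},
#'     \code{green_fraction}) - a continuum of stoichiometries;}
#'   \item{segregated}{the two colours never co-assemble: two pure species
#'     with particle numbers proportional to the expression ratio;}
#'   \item{capped}{red subunits are admitted only up to
#'     \code{ceiling(max_incorporation * n_total_subunits)} per particle;
#'     excess red capacity is filled by green subunits (a limited
#'     incorporation ceiling, e.g. ~30 percent).}
#' }
#' The binomial composition is discretised deterministically: compositions
#' are enumerated and particle counts assigned by largest-remainder
#' rounding of the binomial probabilities, so the output is seed-free.
#'
#' @param n_total_subunits Subunits per assembled particle.
#' @param green_fraction Fraction of green-tagged subunit expression, [0, 1].
#' @param mode One of \code{"mixing"}, \code{"segregated"}, \code{"capped"}.
#' @param max_incorporation Incorporation ceiling for capped mode, (0, 1].
#' @param n_particles Total particles across the mixture.
#' @param diameter_nm Hydrodynamic diameter shared by all species.
#' @param maturation_fraction Emissive fraction passed through to each species.
#' @return A list of \code{\link{species_spec}} objects.
#' @export
make_coassembly_mixture <- function(n_total_subunits, green_fraction,
                                    mode = c("mixing", "segregated", "capped"),
                                    max_incorporation = 1,
                                    n_particles = 13, diameter_nm = 5,
                                    maturation_fraction = 1) {
  mode <- match.arg(mode)
  stopifnot(n_total_subunits >= 1,
            green_fraction >= 0, green_fraction <= 1,
            max_incorporation > 0, max_incorporation <= 1,
            n_particles >= 0)
  n <- as.integer(round(n_total_subunits))

  if (mode == "segregated") {
    n_g <- round(n_particles * green_fraction)
    n_r <- n_particles - n_g
    out <- list()
    if (n_g > 0) out <- c(out, list(species_spec(n, 0, diameter_nm, n_g,
                                                 maturation_fraction)))
    if (n_r > 0) out <- c(out, list(species_spec(0, n, diameter_nm, n_r,
                                                 maturation_fraction)))
    return(out)
  }

  # mixing / capped: enumerate green counts k = 0..n with binomial weights
  k <- 0:n
  p <- stats::dbinom(k, n, green_fraction)
  if (mode == "capped") {
    # truncate red occupancy: red = min(n - k, cap), excess refilled as green
    cap <- ceiling(max_incorporation * n)
    red <- pmin(n - k, cap)
    green <- n - red
  } else {
    green <- k
    red <- n - k
  }
  # collapse duplicate (green, red) compositions created by the cap
  key <- paste(green, red)
  agg <- rowsum(p, key)
  comp <- do.call(rbind, lapply(strsplit(rownames(agg), " "), as.integer))
  p <- as.numeric(agg)

  # largest-remainder rounding of n_particles * p
  raw <- n_particles * p
  base <- floor(raw)
  left <- n_particles - sum(base)
  if (left > 0) {
    add <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[add] <- base[add] + 1
  }
  keep <- which(base > 0)
  lapply(keep, function(i) {
    species_spec(comp[i, 1], comp[i, 2], diameter_nm, base[i],
                 maturation_fraction)
  })
}
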