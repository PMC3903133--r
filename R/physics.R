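#' Stokes-Einstein diffusion coefficient
#'
#' Translational diffusion coefficient of a sphere of hydrodynamic diameter
#' \code{d}: \eqn{D = k_B T / (3 \pi \eta d)}.
#'
#' @param diameter_nm Hydrodynamic diameter in nanometres.
#' @param temperature_K Bath temperature in kelvin.
#' @param viscosity_mPas Solvent viscosity in mPa s (water at 25 C: 0.89).
#' @return Diffusion coefficient in um^2/s.
#' @examples
#' stokes_einstein_diffusion(5, 298, 0.89)  # ~98 um^2/s, a GFP-sized barrel
#' @export
stokes_einstein_diffusion <- function(diameter_nm, temperature_K = 298,
                                      viscosity_mPas = 0.89) {
  if (any(diameter_nm <= 0) || any(temperature_K <= 0) ||
      any(viscosity_mPas <= 0)) {
    stop("diameter, temperature and viscosity must all be positive")
  }
  kb <- 1.380649e-23                      # J/K
  d_m <- diameter_nm * 1e-9
  eta <- viscosity_mPas * 1e-3            # Pa s
  d_si <- kb * temperature_K / (3 * pi * eta * d_m)   # m^2/s
  d_si * 1e12                             # um^2/s
}

#' Characteristic diffusion (residence) time in a Gaussian focal volume
#'
#' \eqn{\tau_D = w_{xy}^2 / (4 D)}: the lateral dwell time of a diffusing
#' particle in a Gaussian detection profile of 1/e^2 radius \code{waist_xy_um}.
#'
#' @param diffusion_um2s Diffusion coefficient in um^2/s.
#' @param waist_xy_um Lateral 1/e^2 waist in um.
#' @return Residence time in seconds.
#' @export
diffusion_time <- function(diffusion_um2s, waist_xy_um = 0.2) {
  if (any(diffusion_um2s <= 0) || any(waist_xy_um <= 0)) {
    stop("diffusion coefficient and waist must be positive")
  }
  waist_xy_um^2 / (4 * diffusion_um2s)
}
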