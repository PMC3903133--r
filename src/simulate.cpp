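#include <Rcpp.h>
using namespace Rcpp;

// Brownian-dynamics photon trace generator.
//
// Each particle performs an independent Gaussian random walk (per-axis step
// s.d. sqrt(2 * D * dt)) inside a cubic box of half-width box_l with periodic
// re-entry.  Per fine bin the green-channel Poisson mean is
//   bg_g*dt + sum_p ng[p] * B_g * PSF(r_p) * dt
// with PSF(r) = exp(-2(x^2+y^2)/wxy^2 - 2 z^2/wz^2); the red-channel mean is
// built analogously from nr[p] and B_r, plus additive crosstalk
// leakage * (green signal mean, background excluded).  Counts are independent
// Poisson variates drawn from R's RNG, so a fixed seed gives an identical
// trace.
//
// ng, nr: emissive fluorophores per particle; d_um2s: diffusion coefficient
// per particle (um^2/s); brightness in Hz per fluorophore at the PSF centre.
// init_pos: optional n x 3 matrix of starting positions (um); if it has zero
// rows, positions are drawn uniformly in the box.
// [[Rcpp::export]]
List sim_trace_cpp(const int n_bins, const double bin_s,
                   const NumericVector ng, const NumericVector nr,
                   const NumericVector d_um2s,
                   const double wxy, const double wz,
                   const double brightness_g_hz, const double brightness_r_hz,
                   const double leakage,
                   const double bg_g_hz, const double bg_r_hz,
                   const double box_l,
                   const NumericMatrix init_pos) {
  const int np = ng.size();
  std::vector<double> x(np), y(np), z(np), sd(np);
  RNGScope scope;

  for (int p = 0; p < np; ++p) {
    if (init_pos.nrow() == np) {
      x[p] = init_pos(p, 0); y[p] = init_pos(p, 1); z[p] = init_pos(p, 2);
    } else {
      x[p] = R::runif(-box_l, box_l);
      y[p] = R::runif(-box_l, box_l);
      z[p] = R::runif(-box_l, box_l);
    }
    sd[p] = std::sqrt(2.0 * d_um2s[p] * bin_s);
  }

  const double cxy = 2.0 / (wxy * wxy), cz = 2.0 / (wz * wz);
  const double span = 2.0 * box_l;
  IntegerVector green(n_bins), red(n_bins);

  for (int t = 0; t < n_bins; ++t) {
    double gsig = 0.0, rsig = 0.0;
    for (int p = 0; p < np; ++p) {
      if (sd[p] > 0.0) {
        x[p] += R::norm_rand() * sd[p];
        y[p] += R::norm_rand() * sd[p];
        z[p] += R::norm_rand() * sd[p];
        // periodic re-entry keeps concentration constant
        if (x[p] > box_l) x[p] -= span; else if (x[p] < -box_l) x[p] += span;
        if (y[p] > box_l) y[p] -= span; else if (y[p] < -box_l) y[p] += span;
        if (z[p] > box_l) z[p] -= span; else if (z[p] < -box_l) z[p] += span;
      }
      const double e = cxy * (x[p] * x[p] + y[p] * y[p]) + cz * z[p] * z[p];
      if (e < 30.0) {  // exp(-30) ~ 1e-13: below any detectable rate
        const double psf = std::exp(-e);
        gsig += ng[p] * psf;
        rsig += nr[p] * psf;
      }
    }
    const double gmean = brightness_g_hz * gsig * bin_s;
    const double rmean = brightness_r_hz * rsig * bin_s + leakage * gmean;
    green[t] = (int) R::rpois(gmean + bg_g_hz * bin_s);
    red[t]   = (int) R::rpois(rmean + bg_r_hz * bin_s);
  }

  return List::create(_["green"] = green, _["red"] = red);
}
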