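#include <Rcpp.h>
using namespace Rcpp;

// Multi-tau autocorrelation on a log-spaced lag grid.
//
// g(T) = <I(t) I(t+T)> / (<I(t)> <I(t+T)>) with symmetric normalisation
// (the two means are taken over the overlapping segments).  Level 0 uses
// lags 1..16 at the native bin width; every further level halves the time
// resolution by averaging adjacent bins and evaluates lags 9..16, giving
// 8 points per octave.  Lag 0 is never reported, so pure shot noise does
// not enter the curve.  For an uncorrelated Poisson stream g ~ 1 at all
// reported lags.
// [[Rcpp::export]]
List multitau_cpp(const NumericVector trace, const double bin_s,
                  const double max_lag_s) {
  std::vector<double> y(trace.begin(), trace.end());
  double w = bin_s;
  std::vector<double> lags, g, mprod;
  int level = 0;

  while ((int) y.size() >= 32) {
    const int lo = (level == 0) ? 1 : 9;
    bool past_max = false;
    for (int k = lo; k <= 16; ++k) {
      const double lag = k * w;
      if (lag > max_lag_s) { past_max = true; break; }
      const size_t n = y.size() - k;
      double s = 0.0, m1 = 0.0, m2 = 0.0;
      for (size_t t = 0; t < n; ++t) {
        s  += y[t] * y[t + k];
        m1 += y[t];
        m2 += y[t + k];
      }
      m1 /= n; m2 /= n;
      lags.push_back(lag);
      g.push_back((m1 > 0.0 && m2 > 0.0) ? (s / n) / (m1 * m2) : NA_REAL);
      mprod.push_back(m1 * m2);
    }
    if (past_max) break;
    // coarsen: average adjacent bins, double the bin width
    const size_t half = y.size() / 2;
    for (size_t i = 0; i < half; ++i) y[i] = 0.5 * (y[2 * i] + y[2 * i + 1]);
    y.resize(half);
    w *= 2.0;
    ++level;
  }

  return List::create(_["lag_s"] = NumericVector(lags.begin(), lags.end()),
                      _["g"] = NumericVector(g.begin(), g.end()),
                      _["mean_product"] = NumericVector(mprod.begin(),
                                                        mprod.end()));
}
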