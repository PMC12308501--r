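#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// Phase lag index for every unordered ROI pair of one epoch.
//
// `phase` is n_roi x n_samples, entries in radians already wrapped to
// (-pi, pi] (as returned by the analytic-signal angle). For each pair (i, j)
// the phase difference phi_i - phi_j is wrapped to (-pi, pi] and the PLI is
// |mean_k sign(dphi_k)| with sign(0) = 0 and sign(+pi) = +1 (the wrap maps
// exact antiphase to +pi). Returns a symmetric n_roi x n_roi matrix with a
// zero diagonal.
// [[Rcpp::export(name = ".pli_matrix_epoch")]]
NumericMatrix pli_matrix_epoch(const NumericMatrix& phase) {
  const int n_roi = phase.nrow();
  const int n = phase.ncol();
  NumericMatrix out(n_roi, n_roi);
  const double pi = M_PI, two_pi = 2.0 * M_PI;

  for (int i = 0; i < n_roi; ++i) {
    for (int j = i + 1; j < n_roi; ++j) {
      long s = 0;
      for (int k = 0; k < n; ++k) {
        // inputs are in (-pi, pi], so the raw difference lies in (-2 pi, 2 pi)
        // and one conditional shift wraps it to (-pi, pi]
        double d = phase(i, k) - phase(j, k);
        if (d <= -pi) d += two_pi;
        else if (d > pi) d -= two_pi;
        if (d > 0.0) ++s;
        else if (d < 0.0) --s;
      }
      double v = std::fabs(static_cast<double>(s) / static_cast<double>(n));
      out(i, j) = v;
      out(j, i) = v;
    }
  }
  return out;
}
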