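#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Glauber (single-site Gibbs) dynamics on a Boltzmann distribution
// p(z) ~ exp(z'Wz/2 + z'b). One sweep = n sequential single-site updates.
// State occupancy is counted once per sweep after the burn-in. Uses R's RNG
// so that set.seed() controls reproducibility.

// [[Rcpp::export]]
List cpp_glauber(NumericMatrix W, NumericVector b, double sweeps,
                 double burnin, IntegerVector init) {
  const int n = b.size();
  std::vector<int> z(n);
  for (int i = 0; i < n; ++i) z[i] = init[i];

  const bool count_states = n <= 16;
  std::vector<double> counts(count_states ? (size_t)1 << n : 0, 0.0);
  NumericVector mz(n);
  NumericMatrix mzz(n, n);

  long idx = 0;
  for (int i = 0; i < n; ++i)
    if (z[i]) idx |= 1L << i;

  const double total = sweeps + burnin;
  double kept = 0.0;
  for (double s = 0; s < total; ++s) {
    for (int i = 0; i < n; ++i) {
      double field = b[i];
      for (int j = 0; j < n; ++j)
        if (z[j]) field += W(i, j);
      const double p = 1.0 / (1.0 + std::exp(-field));
      const int znew = (unif_rand() < p) ? 1 : 0;
      if (znew != z[i]) {
        z[i] = znew;
        idx ^= 1L << i;
      }
    }
    if (s >= burnin) {
      kept += 1.0;
      if (count_states) counts[idx] += 1.0;
      for (int i = 0; i < n; ++i) {
        if (z[i]) {
          mz[i] += 1.0;
          for (int j = i + 1; j < n; ++j)
            if (z[j]) {
              mzz(i, j) += 1.0;
              mzz(j, i) += 1.0;
            }
        }
      }
    }
  }
  for (int i = 0; i < n; ++i) {
    mz[i] /= kept;
    for (int j = 0; j < n; ++j) mzz(i, j) /= kept;
    mzz(i, i) = mz[i];
  }
  return List::create(_["counts"] = wrap(counts), _["mz"] = mz,
                      _["mzz"] = mzz, _["kept"] = kept);
}
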