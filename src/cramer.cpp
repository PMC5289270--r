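#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Baringhaus-Franz two-sample statistic with kernel phi(z) = |z| / 2:
//   T = mn/(m+n) * [ 2/(mn) S_xy - 1/m^2 S_xx - 1/n^2 S_yy ]
// where S_ab are sums of phi over all cross pairs. Computed from a pooled
// absolute-difference matrix so label permutations are cheap.
static double cramer_T(const std::vector<double> &D, int N,
                       const std::vector<int> &idx, int m) {
  // idx: permutation of 0..N-1; first m entries are sample x
  const int n = N - m;
  double sxx = 0.0, syy = 0.0, sxy = 0.0;
  for (int a = 0; a < N; ++a) {
    const bool ax = a < m;
    const int ia = idx[a];
    for (int b = a + 1; b < N; ++b) {
      const double d = D[ia * N + idx[b]];
      const bool bx = b < m;
      if (ax && bx) sxx += d;
      else if (!ax && !bx) syy += d;
      else sxy += d;
    }
  }
  const double mm = (double)m, nn = (double)n;
  // sums above run over unordered pairs; the double sums of the formula
  // run over ordered pairs, hence the factor 2 on every term
  return mm * nn / (mm + nn) * 2.0 *
         (sxy / (mm * nn) - sxx / (mm * mm) - syy / (nn * nn));
}

// [[Rcpp::export]]
List cramer_perm_cpp(NumericVector x, NumericVector y, int n_boot,
                     bool ordinary = false) {
  const int m = x.size(), n = y.size(), N = m + n;
  std::vector<double> pool(N);
  for (int i = 0; i < m; ++i) pool[i] = x[i];
  for (int j = 0; j < n; ++j) pool[m + j] = y[j];
  std::vector<double> D(N * N);
  for (int a = 0; a < N; ++a)
    for (int b = 0; b < N; ++b)
      D[a * N + b] = 0.5 * std::fabs(pool[a] - pool[b]);

  std::vector<int> idx(N);
  for (int i = 0; i < N; ++i) idx[i] = i;
  const double T_obs = cramer_T(D, N, idx, m);

  int ge = 0;
  if (n_boot > 0) {
    for (int b = 0; b < n_boot; ++b) {
      if (ordinary) {
        // ordinary bootstrap: resample pooled observations with
        // replacement for both groups
        for (int i = 0; i < N; ++i)
          idx[i] = (int)(unif_rand() * N);
      } else {
        // label permutation: Fisher-Yates shuffle
        for (int i = 0; i < N; ++i) idx[i] = i;
        for (int i = N - 1; i > 0; --i) {
          int j = (int)(unif_rand() * (i + 1));
          std::swap(idx[i], idx[j]);
        }
      }
      if (cramer_T(D, N, idx, m) >= T_obs) ++ge;
    }
  }
  const double p = n_boot > 0 ? (1.0 + ge) / (1.0 + n_boot) : NA_REAL;
  return List::create(_["statistic"] = T_obs, _["p_value"] = p);
}
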