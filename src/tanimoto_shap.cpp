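// Exact Shapley values for the restricted Tanimoto-kernel coalition game.
//
// For an explained fingerprint x and a support vector s, the game over the
// feature set F (|F| = m) is
//   v(S) = c_S / (a_S + b_S - c_S),  v(S) = 0 if the denominator is 0,
// where a_S, b_S, c_S count on-bits of x, s and x&s inside S. v depends on
// S only through the composition (i, p, q) = counts of (1,1), (1,0), (0,1)
// features in S: v = i / (i + p + q). Features therefore fall into four
// equivalence classes by (x_j, s_j); (0,0) features are dummies and the two
// mismatch classes share one value. Shapley sums over coalitions collapse
// to O(m^2) sums over (i, r = p + q) with hypergeometric weights:
//
//   W(t) = sum_z C(N00, z) * w(t + z),   w(s) = s! (m-s-1)! / m!
//   phi_match = sum_{i,r} C(N11-1, i) C(N10+N01, r) W(i+r)
//               * [ (i+1)/(i+1+r) - i/(i+r) ]
//   phi_mismatch = sum_{i,r} C(N11, i) C(N10+N01-1, r) W(i+r)
//               * [ i/(i+r+1) - i/(i+r) ]
//
// with 0/0 read as 0. Efficiency: sum_j phi_j = v(F) = K(x, s).

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

// per-support-vector class values; phi[0] = matched (1,1), phi[1] = mismatch
void tanimoto_game_class_values(int N11, int Nmis, int N00, int m,
                        const std::vector<double> &lf, double *phi) {
  phi[0] = 0.0;
  phi[1] = 0.0;
  int Tmax = N11 + Nmis;  // coalition sizes i + r run to Tmax - 1
  if (Tmax == 0) return;

  // W(t) = sum_z C(N00, z) w(t+z); every addend is in [0, 1]
  std::vector<double> W(Tmax, 0.0);
  for (int t = 0; t < Tmax; ++t) {
    double acc = 0.0;
    for (int z = 0; z <= N00; ++z) {
      int s = t + z;
      acc += std::exp(lf[N00] - lf[z] - lf[N00 - z] +
                      lf[s] + lf[m - s - 1] - lf[m]);
    }
    W[t] = acc;
  }

  if (N11 >= 1) {
    double acc = 0.0;
    for (int i = 0; i <= N11 - 1; ++i) {
      double lci = lf[N11 - 1] - lf[i] - lf[N11 - 1 - i];
      for (int r = 0; r <= Nmis; ++r) {
        double delta = (double)(i + 1) / (i + 1 + r) -
                       (i + r > 0 ? (double)i / (i + r) : 0.0);
        if (delta == 0.0) continue;
        double lcr = lf[Nmis] - lf[r] - lf[Nmis - r];
        acc += std::exp(lci + lcr) * W[i + r] * delta;
      }
    }
    phi[0] = acc;
  }

  if (Nmis >= 1) {
    double acc = 0.0;
    for (int i = 1; i <= N11; ++i) {  // i = 0 terms vanish
      double lci = lf[N11] - lf[i] - lf[N11 - i];
      for (int r = 0; r <= Nmis - 1; ++r) {
        double delta = (double)i / (i + r + 1) - (double)i / (i + r);
        double lcr = lf[Nmis - 1] - lf[r] - lf[Nmis - 1 - r];
        acc += std::exp(lci + lcr) * W[i + r] * delta;
      }
    }
    phi[1] = acc;
  }
}

}  // namespace

// [[Rcpp::export(name = ".tanimoto_shap_cpp")]]
NumericVector tanimoto_shap_cpp(IntegerVector x, IntegerMatrix S,
                             NumericVector coef) {
  int m = x.size(), nsv = S.nrow();
  if (S.ncol() != m) stop("support-vector dimension mismatch");
  if (coef.size() != nsv) stop("coefficient length mismatch");

  std::vector<double> lf(m + 1);
  lf[0] = 0.0;
  for (int i = 1; i <= m; ++i) lf[i] = lf[i - 1] + std::log((double)i);

  NumericVector phi(m);
  double cls[2];
  for (int k = 0; k < nsv; ++k) {
    if (coef[k] == 0.0) continue;
    int N11 = 0, Nmis = 0;
    for (int j = 0; j < m; ++j) {
      int xj = x[j], sj = S(k, j);
      if (xj == 1 && sj == 1) ++N11;
      else if (xj != sj) ++Nmis;
    }
    int N00 = m - N11 - Nmis;
    tanimoto_game_class_values(N11, Nmis, N00, m, lf, cls);
    for (int j = 0; j < m; ++j) {
      int xj = x[j], sj = S(k, j);
      if (xj == 1 && sj == 1) phi[j] += coef[k] * cls[0];
      else if (xj != sj) phi[j] += coef[k] * cls[1];
    }
  }
  return phi;
}
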