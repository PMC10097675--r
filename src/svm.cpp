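// Sequential minimal optimization for a binary C-SVC with a precomputed
// kernel matrix. Working-set selection is the maximal violating pair;
// the stopping tolerance maps to the usual KKT gap criterion.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export(name = ".svm_smo_cpp")]]
List svm_smo_cpp(NumericMatrix K, IntegerVector y, double C, double tol,
                 int max_iter) {
  int n = K.nrow();
  if (K.ncol() != n || y.size() != n) stop("kernel/label dimension mismatch");
  double eps = std::max(tol, 1e-12);

  std::vector<double> alpha(n, 0.0);
  std::vector<double> f(n, 0.0);  // f_i = sum_j alpha_j y_j K_ij (no bias)

  int iter = 0;
  double m_up = 0.0, M_low = 0.0;
  for (; iter < max_iter; ++iter) {
    // maximal violating pair on -y_i g_i = y_i - f_i
    int i_up = -1, i_low = -1;
    m_up = -HUGE_VAL; M_low = HUGE_VAL;
    for (int i = 0; i < n; ++i) {
      double v = y[i] - f[i];
      bool up = (y[i] == 1 && alpha[i] < C) || (y[i] == -1 && alpha[i] > 0);
      bool low = (y[i] == 1 && alpha[i] > 0) || (y[i] == -1 && alpha[i] < C);
      if (up && v > m_up) { m_up = v; i_up = i; }
      if (low && v < M_low) { M_low = v; i_low = i; }
    }
    if (i_up < 0 || i_low < 0 || m_up - M_low < eps) break;

    int i = i_up, j = i_low;
    double Ei = f[i] - y[i], Ej = f[j] - y[j];
    double eta = K(i, i) + K(j, j) - 2.0 * K(i, j);
    if (eta <= 0) eta = 1e-12;

    double aj_old = alpha[j], ai_old = alpha[i];
    double L, H;
    if (y[i] != y[j]) {
      L = std::max(0.0, aj_old - ai_old);
      H = std::min(C, C + aj_old - ai_old);
    } else {
      L = std::max(0.0, ai_old + aj_old - C);
      H = std::min(C, ai_old + aj_old);
    }
    if (H - L < 1e-15) break;

    double aj = aj_old + y[j] * (Ei - Ej) / eta;
    if (aj < L) aj = L;
    if (aj > H) aj = H;
    if (std::fabs(aj - aj_old) < 1e-14) break;
    double ai = ai_old + (double)(y[i] * y[j]) * (aj_old - aj);

    alpha[i] = ai;
    alpha[j] = aj;
    double di = (ai - ai_old) * y[i], dj = (aj - aj_old) * y[j];
    for (int k = 0; k < n; ++k) f[k] += di * K(i, k) + dj * K(j, k);
  }

  // bias: mean of y_i - f_i over free support vectors, else midpoint of the
  // KKT interval
  double b = 0.0;
  int nfree = 0;
  for (int i = 0; i < n; ++i) {
    if (alpha[i] > 1e-12 && alpha[i] < C - 1e-12) {
      b += y[i] - f[i];
      ++nfree;
    }
  }
  if (nfree > 0) {
    b /= nfree;
  } else {
    b = (m_up + M_low) / 2.0;
    if (!std::isfinite(b)) b = 0.0;
  }
  return List::create(_["alpha"] = wrap(alpha), _["b"] = b,
                      _["iterations"] = iter);
}
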