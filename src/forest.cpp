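// Random forest for binary fingerprints: CART trees with gini/entropy
// impurity, per-node feature subsampling and optional bootstrap, plus an
// exact interventional Shapley engine over the fitted ensemble.
//
// All randomness comes from R's RNG so fits are reproducible under
// set.seed() in the calling R code.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct TreeBuilder {
  std::vector<int> feature;   // -1 for leaf
  std::vector<int> left;
  std::vector<int> right;
  std::vector<double> value;  // P(class 1) at node
  std::vector<int> nsamp;

  int new_node(double val, int n) {
    feature.push_back(-1);
    left.push_back(-1);
    right.push_back(-1);
    value.push_back(val);
    nsamp.push_back(n);
    return (int)feature.size() - 1;
  }
};

inline double impurity(int n0, int n1, int criterion) {
  int n = n0 + n1;
  if (n == 0) return 0.0;
  double p0 = (double)n0 / n, p1 = (double)n1 / n;
  if (criterion == 0) {            // gini
    return 1.0 - p0 * p0 - p1 * p1;
  }
  double h = 0.0;                  // entropy (natural log; base cancels)
  if (p0 > 0) h -= p0 * std::log(p0);
  if (p1 > 0) h -= p1 * std::log(p1);
  return h;
}

// partial Fisher-Yates draw of mtry candidate features
void sample_features(std::vector<int> &pool, int mtry, std::vector<int> &out) {
  int m = (int)pool.size();
  out.clear();
  for (int k = 0; k < mtry; ++k) {
    int j = k + (int)std::floor(unif_rand() * (m - k));
    if (j >= m) j = m - 1;
    std::swap(pool[k], pool[j]);
    out.push_back(pool[k]);
  }
}

struct Grower {
  const IntegerMatrix &X;
  const IntegerVector &y;
  int criterion;
  int min_samples_split;
  int mtry;
  TreeBuilder tb;
  std::vector<int> pool;

  Grower(const IntegerMatrix &X_, const IntegerVector &y_, int crit,
         int mss, int mtry_)
      : X(X_), y(y_), criterion(crit), min_samples_split(mss), mtry(mtry_) {
    pool.resize(X.ncol());
    for (int j = 0; j < X.ncol(); ++j) pool[j] = j;
  }

  int grow(std::vector<int> &idx) {
    int n = (int)idx.size();
    int n1 = 0;
    for (int i : idx) n1 += y[i];
    int n0 = n - n1;
    double p1 = (double)n1 / n;
    if (n0 == 0 || n1 == 0 || n < min_samples_split)
      return tb.new_node(p1, n);

    double parent = impurity(n0, n1, criterion);
    std::vector<int> cand;
    sample_features(pool, mtry, cand);

    int best_j = -1;
    double best_gain = 1e-12;
    for (int j : cand) {
      int nl = 0, nl1 = 0;
      for (int i : idx) {
        if (X(i, j) == 0) { ++nl; nl1 += y[i]; }
      }
      int nr = n - nl;
      if (nl == 0 || nr == 0) continue;
      int nr1 = n1 - nl1;
      double child = ((double)nl / n) * impurity(nl - nl1, nl1, criterion) +
                     ((double)nr / n) * impurity(nr - nr1, nr1, criterion);
      double gain = parent - child;
      if (gain > best_gain) { best_gain = gain; best_j = j; }
    }
    if (best_j < 0) return tb.new_node(p1, n);

    std::vector<int> li, ri;
    for (int i : idx) {
      if (X(i, best_j) == 0) li.push_back(i); else ri.push_back(i);
    }
    int node = tb.new_node(p1, n);
    tb.feature[node] = best_j;
    int l = grow(li);
    int r = grow(ri);
    tb.left[node] = l;
    tb.right[node] = r;
    return node;
  }
};

inline double tree_leaf_prob(const IntegerVector &feature,
                             const IntegerVector &left,
                             const IntegerVector &right,
                             const NumericVector &value,
                             const int *x) {
  int node = 0;
  while (feature[node] >= 0)
    node = (x[feature[node]] == 0) ? left[node] : right[node];
  return value[node];
}

// Exact interventional Shapley values of one tree for one (x, z) pair.
//
// The coalition game is v(S) = leaf value reached by following x on
// features in S and z elsewhere. Descending the tree, a node where x and z
// take the same branch is traversed directly; a disagreement node splits
// the recursion into "feature in S" (x branch) and "feature out of S"
// (z branch). Every reachable leaf L therefore carries a pair of disjoint
// feature sets (A_L: must be in S, B_L: must be out), and v is a signed
// sum of set-guard games u(S) = 1[A ⊆ S, B ∩ S = ∅] whose Shapley values
// have the closed forms
//   phi_j = (a-1)! b! / (a+b)!   for j in A,
//   phi_j = -a! (b-1)! / (a+b)!  for j in B,   a = |A|, b = |B|.
struct ShapWalker {
  const IntegerVector &feature;
  const IntegerVector &left;
  const IntegerVector &right;
  const NumericVector &value;
  const int *x;
  const int *z;
  std::vector<int> state;  // 0 free, 1 follow x, 2 follow z
  std::vector<int> A, B;
  double *phi;
  double w;                // 1 / (n_trees * n_background)
  const std::vector<double> &lf;  // log factorials

  ShapWalker(const IntegerVector &f, const IntegerVector &l,
             const IntegerVector &r, const NumericVector &v, int m,
             double *phi_, double w_, const std::vector<double> &lf_)
      : feature(f), left(l), right(r), value(v), x(nullptr), z(nullptr),
        state(m, 0), phi(phi_), w(w_), lf(lf_) {}

  void leaf(double val) {
    int a = (int)A.size(), b = (int)B.size();
    if (a == 0 && b == 0) return;  // constant term, no attribution
    if (a > 0) {
      double wa = std::exp(lf[a - 1] + lf[b] - lf[a + b]);
      for (int j : A) phi[j] += w * val * wa;
    }
    if (b > 0) {
      double wb = std::exp(lf[a] + lf[b - 1] - lf[a + b]);
      for (int j : B) phi[j] -= w * val * wb;
    }
  }

  void walk(int node) {
    int f = feature[node];
    if (f < 0) { leaf(value[node]); return; }
    int xc = (x[f] == 0) ? left[node] : right[node];
    int zc = (z[f] == 0) ? left[node] : right[node];
    if (xc == zc) { walk(xc); return; }
    switch (state[f]) {
      case 1: walk(xc); break;
      case 2: walk(zc); break;
      default:
        state[f] = 1; A.push_back(f);
        walk(xc);
        A.pop_back();
        state[f] = 2; B.push_back(f);
        walk(zc);
        B.pop_back();
        state[f] = 0;
    }
  }
};

}  // namespace

// [[Rcpp::export(name = ".rf_fit_cpp")]]
List rf_fit_cpp(IntegerMatrix X, IntegerVector y, int n_estimators,
                int criterion, int min_samples_split, int max_features_mode,
                bool bootstrap) {
  int n = X.nrow(), m = X.ncol();
  int mtry;
  if (max_features_mode == 0)
    mtry = std::max(1, (int)std::floor(std::sqrt((double)m)));
  else
    mtry = std::max(1, (int)std::floor(std::log2((double)m)));

  List trees(n_estimators);
  for (int t = 0; t < n_estimators; ++t) {
    std::vector<int> idx(n);
    if (bootstrap) {
      for (int i = 0; i < n; ++i) {
        int k = (int)std::floor(unif_rand() * n);
        if (k >= n) k = n - 1;
        idx[i] = k;
      }
    } else {
      for (int i = 0; i < n; ++i) idx[i] = i;
    }
    Grower g(X, y, criterion, min_samples_split, mtry);
    g.grow(idx);
    trees[t] = List::create(
        _["feature"] = wrap(g.tb.feature), _["left"] = wrap(g.tb.left),
        _["right"] = wrap(g.tb.right), _["value"] = wrap(g.tb.value),
        _["nsamp"] = wrap(g.tb.nsamp));
  }
  return List::create(_["trees"] = trees, _["n_features"] = m);
}

// [[Rcpp::export(name = ".rf_predict_cpp")]]
NumericVector rf_predict_cpp(List forest, IntegerMatrix X) {
  List trees = forest["trees"];
  int n = X.nrow(), T = trees.size();
  NumericVector out(n);
  std::vector<int> row(X.ncol());
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < X.ncol(); ++j) row[j] = X(i, j);
    double s = 0.0;
    for (int t = 0; t < T; ++t) {
      List tr = trees[t];
      IntegerVector f = tr["feature"], l = tr["left"], r = tr["right"];
      NumericVector v = tr["value"];
      s += tree_leaf_prob(f, l, r, v, row.data());
    }
    out[i] = s / T;
  }
  return out;
}

// [[Rcpp::export(name = ".rf_shap_cpp")]]
List rf_shap_cpp(List forest, IntegerVector x, IntegerMatrix Z) {
  List trees = forest["trees"];
  int m = as<int>(forest["n_features"]);
  int T = trees.size(), nz = Z.nrow();
  if (x.size() != m) stop("fingerprint length does not match the model");
  if (nz == 0) stop("background matrix must be non-empty");

  std::vector<double> lf(m + 2);
  lf[0] = 0.0;
  for (int i = 1; i <= m + 1; ++i) lf[i] = lf[i - 1] + std::log((double)i);

  NumericVector phi(m);
  double w = 1.0 / ((double)T * nz);
  std::vector<int> zrow(m);
  double base = 0.0, fx = 0.0;

  for (int t = 0; t < T; ++t) {
    List tr = trees[t];
    IntegerVector f = tr["feature"], l = tr["left"], r = tr["right"];
    NumericVector v = tr["value"];
    fx += tree_leaf_prob(f, l, r, v, x.begin()) / T;
    ShapWalker walker(f, l, r, v, m, phi.begin(), w, lf);
    walker.x = x.begin();
    for (int iz = 0; iz < nz; ++iz) {
      for (int j = 0; j < m; ++j) zrow[j] = Z(iz, j);
      base += tree_leaf_prob(f, l, r, v, zrow.data()) * w;
      walker.z = zrow.data();
      walker.walk(0);
    }
  }
  return List::create(_["phi"] = phi, _["base"] = base, _["output"] = fx);
}
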