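#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Centered rolling statistics with shrunken edge windows.
//
// For a window of w samples, the window at index i (0-based) covers
// [i - floor((w-1)/2), i + (w - 1 - floor((w-1)/2))], clipped to the series.
// With the default 2-s window at 8 Hz (w = 16) that is 7 samples back and
// 8 forward. stat: 0 = mean, 1 = min, 2 = max.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector roll_stat_cpp(NumericVector x, int w, int stat) {
  int n = x.size();
  if (n == 0) stop("empty series");
  if (w < 1) stop("window must cover at least one sample");
  int left = (w - 1) / 2;
  int right = w - 1 - left;
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    int lo = std::max(0, i - left);
    int hi = std::min(n - 1, i + right);
    if (stat == 0) {
      double s = 0.0;
      for (int j = lo; j <= hi; ++j) s += x[j];
      out[i] = s / (hi - lo + 1);
    } else if (stat == 1) {
      double m = x[lo];
      for (int j = lo + 1; j <= hi; ++j) m = std::min(m, x[j]);
      out[i] = m;
    } else {
      double m = x[lo];
      for (int j = lo + 1; j <= hi; ++j) m = std::max(m, x[j]);
      out[i] = m;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Random forest: CART trees, Gini impurity, bootstrap resampling, mtry
// features per split, majority vote. Uses R's RNG so results are
// reproducible under set.seed().
// ---------------------------------------------------------------------------

struct Tree {
  std::vector<int> feat;     // -1 for leaf
  std::vector<double> thr;
  std::vector<int> left, right;
  std::vector<int> pred;     // majority class at node (0-based)
};

static inline double gini_from_counts(const std::vector<int>& cnt, int n) {
  if (n == 0) return 0.0;
  double g = 1.0;
  for (size_t c = 0; c < cnt.size(); ++c) {
    double f = (double)cnt[c] / n;
    g -= f * f;
  }
  return g;
}

static int grow_node(const NumericMatrix& X, const IntegerVector& y,
                     std::vector<int>& idx, int lo, int hi, int n_class,
                     int mtry, int min_node, int depth, int max_depth,
                     Tree& tr) {
  int n = hi - lo;
  std::vector<int> cnt(n_class, 0);
  for (int i = lo; i < hi; ++i) cnt[y[idx[i]]]++;
  int best_cls = 0;
  for (int c = 1; c < n_class; ++c)
    if (cnt[c] > cnt[best_cls]) best_cls = c;
  bool pure = (cnt[best_cls] == n);

  int node = (int)tr.feat.size();
  tr.feat.push_back(-1);
  tr.thr.push_back(0.0);
  tr.left.push_back(-1);
  tr.right.push_back(-1);
  tr.pred.push_back(best_cls);

  if (pure || n < 2 * min_node || depth >= max_depth) return node;

  int p = X.ncol();
  // partial Fisher-Yates to pick mtry distinct features
  std::vector<int> feats(p);
  for (int j = 0; j < p; ++j) feats[j] = j;
  int m = std::min(mtry, p);
  for (int j = 0; j < m; ++j) {
    int k = j + (int)(unif_rand() * (p - j));
    if (k >= p) k = p - 1;
    std::swap(feats[j], feats[k]);
  }

  double parent_imp = gini_from_counts(cnt, n);
  double best_gain = 1e-12;
  int best_f = -1;
  double best_thr = 0.0;

  std::vector<std::pair<double, int> > v(n);
  std::vector<int> lc(n_class);
  for (int jj = 0; jj < m; ++jj) {
    int f = feats[jj];
    for (int i = 0; i < n; ++i) {
      int r = idx[lo + i];
      v[i] = std::make_pair(X(r, f), y[r]);
    }
    std::sort(v.begin(), v.end());
    std::fill(lc.begin(), lc.end(), 0);
    int ln = 0;
    for (int k = 0; k < n - 1; ++k) {
      lc[v[k].second]++;
      ln++;
      if (v[k + 1].first <= v[k].first) continue;
      if (ln < min_node || (n - ln) < min_node) continue;
      double gl = gini_from_counts(lc, ln);
      double gr = 1.0;
      for (int c = 0; c < n_class; ++c) {
        double fr = (double)(cnt[c] - lc[c]) / (n - ln);
        gr -= fr * fr;
      }
      double gain = parent_imp -
        ((double)ln * gl + (double)(n - ln) * gr) / n;
      if (gain > best_gain) {
        best_gain = gain;
        best_f = f;
        best_thr = 0.5 * (v[k].first + v[k + 1].first);
      }
    }
  }
  if (best_f < 0) return node;

  // partition idx[lo, hi) by the chosen split
  int mid = lo;
  for (int i = lo; i < hi; ++i)
    if (X(idx[i], best_f) <= best_thr) {
      std::swap(idx[i], idx[mid]);
      ++mid;
    }
  if (mid == lo || mid == hi) return node;  // degenerate; keep leaf

  tr.feat[node] = best_f;
  tr.thr[node] = best_thr;
  tr.left[node] = grow_node(X, y, idx, lo, mid, n_class, mtry, min_node,
                            depth + 1, max_depth, tr);
  tr.right[node] = grow_node(X, y, idx, mid, hi, n_class, mtry, min_node,
                             depth + 1, max_depth, tr);
  return node;
}

// [[Rcpp::export]]
List rf_train_cpp(NumericMatrix X, IntegerVector y, int n_class, int n_trees,
                  int mtry, int min_node, int max_depth) {
  RNGScope scope;
  int n = X.nrow();
  if (n == 0) stop("empty training set");
  List forest(n_trees);
  std::vector<int> idx(n);
  for (int t = 0; t < n_trees; ++t) {
    for (int i = 0; i < n; ++i) {
      int k = (int)(unif_rand() * n);
      if (k >= n) k = n - 1;
      idx[i] = k;  // bootstrap sample
    }
    Tree tr;
    grow_node(X, y, idx, 0, n, n_class, mtry, min_node, 0, max_depth, tr);
    forest[t] = List::create(_["feat"] = wrap(tr.feat),
                             _["thr"] = wrap(tr.thr),
                             _["left"] = wrap(tr.left),
                             _["right"] = wrap(tr.right),
                             _["pred"] = wrap(tr.pred));
  }
  return forest;
}

// [[Rcpp::export]]
IntegerVector rf_predict_cpp(List forest, NumericMatrix X, int n_class) {
  int n = X.nrow(), nt = forest.size();
  std::vector<std::vector<int> > votes(n, std::vector<int>(n_class, 0));
  for (int t = 0; t < nt; ++t) {
    List tr = forest[t];
    IntegerVector feat = tr["feat"];
    NumericVector thr = tr["thr"];
    IntegerVector left = tr["left"];
    IntegerVector right = tr["right"];
    IntegerVector pred = tr["pred"];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (feat[node] >= 0) {
        node = (X(i, feat[node]) <= thr[node]) ? left[node] : right[node];
      }
      votes[i][pred[node]]++;
    }
  }
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    int best = 0;
    for (int c = 1; c < n_class; ++c)
      if (votes[i][c] > votes[i][best]) best = c;  // ties -> lowest class
    out[i] = best;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Multinomial log-likelihood for the ethogram model (hot path: called once
// per Metropolis proposal). beta is the 3 x 5 period-logit matrix
// (column-major), u the n_ind x re_dim random-effect matrix; effects are
// centered across individuals inside the likelihood.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
double behavior_ll_cpp(NumericMatrix C, IntegerVector period_idx,
                       IntegerVector ind_idx, NumericVector beta,
                       NumericVector u, int n_ind, int re_dim) {
  int ncell = C.nrow();
  // centered random effects, expanded to 5 columns
  std::vector<double> Uc(n_ind * 5, 0.0);
  for (int j = 0; j < re_dim; ++j) {
    double m = 0.0;
    for (int i = 0; i < n_ind; ++i) m += u[j * n_ind + i];
    m /= n_ind;
    for (int i = 0; i < n_ind; ++i) {
      double val = u[j * n_ind + i] - m;
      if (re_dim == 1) {
        for (int k = 0; k < 5; ++k) Uc[k * n_ind + i] = val;
      } else {
        Uc[j * n_ind + i] = val;
      }
    }
  }
  double ll = 0.0;
  double L[6];
  for (int r = 0; r < ncell; ++r) {
    int pd = period_idx[r] - 1, id = ind_idx[r] - 1;
    L[0] = 0.0;
    double mx = 0.0;
    for (int k = 0; k < 5; ++k) {
      L[k + 1] = beta[k * 3 + pd] + Uc[k * n_ind + id];
      if (L[k + 1] > mx) mx = L[k + 1];
    }
    double se = 0.0;
    for (int k = 0; k < 6; ++k) se += std::exp(L[k] - mx);
    double lse = mx + std::log(se);
    for (int k = 0; k < 6; ++k) ll += C(r, k) * (L[k] - lse);
  }
  return ll;
}
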