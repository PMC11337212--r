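// Random-forest estimator (classification by averaged leaf class
// fractions, regression by averaged leaf means) with bootstrap bagging,
// per-node feature subsampling and optional case weights. Implemented from
// scratch because the runtime environment ships no R tree-model package.
// Trees are stored as flat arrays so prediction and Saabas-style path
// attribution (per-feature contributions that sum exactly to
// prediction - base value) share one traversal.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <random>
#include <vector>

using namespace Rcpp;

namespace {

struct Tree {
  std::vector<int> feat;     // -1 for leaf
  std::vector<double> thr;
  std::vector<int> left, right;
  std::vector<double> value; // weighted mean of y at node
};

struct Builder {
  const NumericMatrix& X;
  const NumericVector& y;
  const NumericVector& w;
  int max_depth, min_leaf, mtry;
  std::mt19937& rng;
  Tree tree;

  Builder(const NumericMatrix& X_, const NumericVector& y_,
          const NumericVector& w_, int max_depth_, int min_leaf_, int mtry_,
          std::mt19937& rng_)
      : X(X_), y(y_), w(w_), max_depth(max_depth_), min_leaf(min_leaf_),
        mtry(mtry_), rng(rng_) {}

  int make_node(const std::vector<int>& idx, int depth) {
    double sw = 0.0, swy = 0.0;
    for (int i : idx) { sw += w[i]; swy += w[i] * y[i]; }
    double node_val = (sw > 0.0) ? swy / sw : 0.0;

    int node = (int)tree.feat.size();
    tree.feat.push_back(-1);
    tree.thr.push_back(0.0);
    tree.left.push_back(-1);
    tree.right.push_back(-1);
    tree.value.push_back(node_val);

    int n = (int)idx.size();
    bool pure = true;
    for (int i : idx) if (y[i] != y[idx[0]]) { pure = false; break; }
    if (pure || n < 2 * min_leaf ||
        (max_depth > 0 && depth >= max_depth)) {
      return node;
    }

    // sample mtry feature candidates without replacement
    int p = X.ncol();
    std::vector<int> feats(p);
    for (int j = 0; j < p; ++j) feats[j] = j;
    int m = std::min(mtry, p);
    for (int j = 0; j < m; ++j) {
      std::uniform_int_distribution<int> d(j, p - 1);
      std::swap(feats[j], feats[d(rng)]);
    }

    // parent weighted SSE-equivalent: swyy - swy^2/sw; constant term
    // cancels, so maximize  swyL^2/swL + swyR^2/swR.
    double best_gain = -1.0;
    int best_feat = -1, best_cut = -1;
    double best_thr = 0.0;
    std::vector<int> ord(idx);
    std::vector<int> best_ord;

    for (int jj = 0; jj < m; ++jj) {
      int j = feats[jj];
      std::sort(ord.begin(), ord.end(), [&](int a, int b) {
        double xa = X(a, j), xb = X(b, j);
        if (xa != xb) return xa < xb;
        return a < b;
      });
      double swL = 0.0, swyL = 0.0;
      for (int k = 0; k + 1 < n; ++k) {
        int i = ord[k];
        swL += w[i]; swyL += w[i] * y[i];
        if (X(ord[k], j) == X(ord[k + 1], j)) continue;
        int nL = k + 1, nR = n - nL;
        if (nL < min_leaf || nR < min_leaf) continue;
        double swR = sw - swL, swyR = swy - swyL;
        if (swL <= 0.0 || swR <= 0.0) continue;
        double gain = swyL * swyL / swL + swyR * swyR / swR;
        if (gain > best_gain + 1e-12) {
          best_gain = gain; best_feat = j; best_cut = k;
          best_thr = 0.5 * (X(ord[k], j) + X(ord[k + 1], j));
          best_ord = ord;
        }
      }
    }

    double parent_score = (sw > 0.0) ? swy * swy / sw : 0.0;
    if (best_feat < 0 || best_gain <= parent_score + 1e-12) {
      return node; // no impurity decrease
    }

    std::vector<int> li(best_ord.begin(), best_ord.begin() + best_cut + 1);
    std::vector<int> ri(best_ord.begin() + best_cut + 1, best_ord.end());
    tree.feat[node] = best_feat;
    tree.thr[node] = best_thr;
    int l = make_node(li, depth + 1);
    int r = make_node(ri, depth + 1);
    tree.left[node] = l;
    tree.right[node] = r;
    return node;
  }
};

List tree_to_list(const Tree& t) {
  return List::create(_["feat"] = wrap(t.feat), _["thr"] = wrap(t.thr),
                      _["left"] = wrap(t.left), _["right"] = wrap(t.right),
                      _["value"] = wrap(t.value));
}

inline int descend(const IntegerVector& feat, const NumericVector& thr,
                   const IntegerVector& left, const IntegerVector& right,
                   const NumericMatrix& X, int row) {
  int node = 0;
  while (feat[node] >= 0) {
    node = (X(row, feat[node]) <= thr[node]) ? left[node] : right[node];
  }
  return node;
}

} // namespace

// [[Rcpp::export]]
List forest_fit_cpp(NumericMatrix X, NumericVector y, int n_trees,
                    int max_depth, int min_leaf, int mtry,
                    NumericVector case_w, int seed) {
  int n = X.nrow();
  if (n == 0) stop("empty training data");
  std::mt19937 rng((unsigned)seed);
  List trees(n_trees);
  std::uniform_int_distribution<int> pick(0, n - 1);
  for (int b = 0; b < n_trees; ++b) {
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = pick(rng);
    std::sort(idx.begin(), idx.end());
    Builder builder(X, y, case_w, max_depth, min_leaf, mtry, rng);
    builder.make_node(idx, 0);
    trees[b] = tree_to_list(builder.tree);
  }
  return trees;
}

// [[Rcpp::export]]
NumericVector forest_predict_cpp(List trees, NumericMatrix X) {
  int n = X.nrow(), B = trees.size();
  NumericVector out(n);
  for (int b = 0; b < B; ++b) {
    List t = trees[b];
    IntegerVector feat = t["feat"], left = t["left"], right = t["right"];
    NumericVector thr = t["thr"], value = t["value"];
    for (int i = 0; i < n; ++i) {
      out[i] += value[descend(feat, thr, left, right, X, i)];
    }
  }
  for (int i = 0; i < n; ++i) out[i] /= B;
  return out;
}

// [[Rcpp::export]]
List forest_attribute_cpp(List trees, NumericMatrix X) {
  int n = X.nrow(), p = X.ncol(), B = trees.size();
  NumericMatrix contrib(n, p);
  double base = 0.0;
  for (int b = 0; b < B; ++b) {
    List t = trees[b];
    IntegerVector feat = t["feat"], left = t["left"], right = t["right"];
    NumericVector thr = t["thr"], value = t["value"];
    base += value[0];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (feat[node] >= 0) {
        int child = (X(i, feat[node]) <= thr[node]) ? left[node]
                                                    : right[node];
        contrib(i, feat[node]) += value[child] - value[node];
        node = child;
      }
    }
  }
  base /= B;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < p; ++j) contrib(i, j) /= B;
  return List::create(_["base"] = base, _["contributions"] = contrib);
}

// [[Rcpp::export]]
String fnv1a_hash_cpp(CharacterVector parts) {
  // 64-bit FNV-1a over the sorted, concatenated inputs; used for
  // training-set digests (no digest package in the environment).
  std::vector<std::string> v(parts.size());
  for (int i = 0; i < parts.size(); ++i) v[i] = as<std::string>(parts[i]);
  std::sort(v.begin(), v.end());
  uint64_t h = 1469598103934665603ULL;
  for (const auto& s : v) {
    for (unsigned char c : s) { h ^= c; h *= 1099511628211ULL; }
    h ^= (unsigned char)'\n'; h *= 1099511628211ULL;
  }
  char buf[17];
  snprintf(buf, sizeof(buf), "%016llx", (unsigned long long)h);
  return String(buf);
}
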