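// Random-forest classifier (Gini CART trees, bagging, per-split feature
// subsampling) plus the bootstrap x permutation-sampling Shapley loop.
// Written here because no forest package ships with the target R stack and
// the iterative pipeline needs compiled speed on one CPU.
#include <Rcpp.h>
#include <random>
#include <unordered_map>
#include <algorithm>
#include <vector>
#include <cstdint>

using namespace Rcpp;

namespace {

struct RFParams {
  int n_trees;
  int max_depth;   // <= 0 means unlimited
  int mtry;
  bool bootstrap;
  int min_leaf;
  int min_split;
};

struct Forest {
  std::vector<int> feature;       // -1 marks a leaf
  std::vector<double> threshold;
  std::vector<int> left, right;   // absolute node indices
  std::vector<double> value;      // leaf fraction of class 1
  std::vector<int> root;          // root node per tree
};

struct Scratch {
  std::vector<double> xs;
  std::vector<int> ys;
  std::vector<int> order;
  std::vector<int> feats;
};

// Build one node over rows idx[lo, hi); returns node index.
int build_node(const double* X, const int* y, int n, int p,
               std::vector<int>& idx, int lo, int hi, int depth,
               const RFParams& P, std::mt19937& rng, Forest& F, Scratch& S) {
  const int m = hi - lo;
  int n1 = 0;
  for (int i = lo; i < hi; ++i) n1 += y[idx[i]];
  const int n0 = m - n1;

  auto make_leaf = [&]() {
    int node = (int)F.feature.size();
    F.feature.push_back(-1);
    F.threshold.push_back(0.0);
    F.left.push_back(-1);
    F.right.push_back(-1);
    F.value.push_back(m > 0 ? (double)n1 / m : 0.5);
    return node;
  };

  if (n1 == 0 || n0 == 0 || m < P.min_split || m < 2 * P.min_leaf ||
      (P.max_depth > 0 && depth >= P.max_depth))
    return make_leaf();

  // sample mtry features without replacement (partial Fisher-Yates)
  std::vector<int>& feats = S.feats;
  if ((int)feats.size() != p) {
    feats.resize(p);
    for (int j = 0; j < p; ++j) feats[j] = j;
  }
  int mtry = std::min(P.mtry, p);
  for (int j = 0; j < mtry; ++j) {
    std::uniform_int_distribution<int> U(j, p - 1);
    std::swap(feats[j], feats[U(rng)]);
  }

  const double parent_cost = (double)n0 * n1 / m;
  double best_cost = parent_cost - 1e-12;
  int best_f = -1;
  double best_thr = 0.0;

  std::vector<double>& xs = S.xs;
  std::vector<int>& ys = S.ys;
  std::vector<int>& order = S.order;
  xs.resize(m); ys.resize(m); order.resize(m);

  for (int j = 0; j < mtry; ++j) {
    const int f = feats[j];
    const double* col = X + (size_t)f * n;
    for (int i = 0; i < m; ++i) {
      xs[i] = col[idx[lo + i]];
      order[i] = i;
    }
    std::sort(order.begin(), order.end(),
              [&](int a, int b) { return xs[a] < xs[b]; });
    // left-scan class-1 counts over the sorted column
    int l1 = 0;
    for (int i = 0; i < m - 1; ++i) {
      l1 += y[idx[lo + order[i]]];
      const int nl = i + 1, nr = m - nl;
      if (xs[order[i + 1]] <= xs[order[i]]) continue;  // tie, no cut here
      if (nl < P.min_leaf || nr < P.min_leaf) continue;
      const int l0 = nl - l1, r1 = n1 - l1, r0 = nr - r1;
      const double cost = (double)l0 * l1 / nl + (double)r0 * r1 / nr;
      if (cost < best_cost) {
        best_cost = cost;
        best_f = f;
        best_thr = 0.5 * (xs[order[i]] + xs[order[i + 1]]);
      }
    }
  }

  if (best_f < 0) return make_leaf();

  // partition idx[lo,hi) on the chosen cut
  const double* col = X + (size_t)best_f * n;
  int mid = lo;
  for (int i = lo; i < hi; ++i)
    if (col[idx[i]] <= best_thr) std::swap(idx[i], idx[mid++]);
  if (mid == lo || mid == hi) return make_leaf();  // numeric safety

  int node = (int)F.feature.size();
  F.feature.push_back(best_f);
  F.threshold.push_back(best_thr);
  F.left.push_back(-2);
  F.right.push_back(-2);
  F.value.push_back((double)n1 / m);

  int l = build_node(X, y, n, p, idx, lo, mid, depth + 1, P, rng, F, S);
  int r = build_node(X, y, n, p, idx, mid, hi, depth + 1, P, rng, F, S);
  F.left[node] = l;
  F.right[node] = r;
  return node;
}

Forest train_forest(const NumericMatrix& X, const IntegerVector& y,
                    const RFParams& P, std::mt19937& rng) {
  const int n = X.nrow(), p = X.ncol();
  Forest F;
  Scratch S;
  std::vector<int> idx(n);
  std::uniform_int_distribution<int> U(0, n - 1);
  for (int t = 0; t < P.n_trees; ++t) {
    if (P.bootstrap) {
      for (int i = 0; i < n; ++i) idx[i] = U(rng);
    } else {
      for (int i = 0; i < n; ++i) idx[i] = i;
    }
    F.root.push_back(build_node(REAL(X), INTEGER(y), n, p, idx, 0, n, 0, P,
                                rng, F, S));
  }
  return F;
}

double forest_prob_row(const Forest& F, const double* x) {
  double s = 0.0;
  for (size_t t = 0; t < F.root.size(); ++t) {
    int node = F.root[t];
    while (F.feature[node] >= 0)
      node = x[F.feature[node]] <= F.threshold[node] ? F.left[node]
                                                     : F.right[node];
    s += F.value[node];
  }
  return s / F.root.size();
}

List forest_to_list(const Forest& F) {
  return List::create(_["feature"] = wrap(F.feature),
                      _["threshold"] = wrap(F.threshold),
                      _["left"] = wrap(F.left), _["right"] = wrap(F.right),
                      _["value"] = wrap(F.value), _["root"] = wrap(F.root));
}

Forest forest_from_list(const List& L) {
  Forest F;
  F.feature = as<std::vector<int> >(L["feature"]);
  F.threshold = as<std::vector<double> >(L["threshold"]);
  F.left = as<std::vector<int> >(L["left"]);
  F.right = as<std::vector<int> >(L["right"]);
  F.value = as<std::vector<double> >(L["value"]);
  F.root = as<std::vector<int> >(L["root"]);
  return F;
}

RFParams make_params(int n_trees, int max_depth, int mtry, bool bootstrap,
                     int min_leaf, int min_split) {
  RFParams P;
  P.n_trees = n_trees;
  P.max_depth = max_depth;
  P.mtry = std::max(1, mtry);
  P.bootstrap = bootstrap;
  P.min_leaf = std::max(1, min_leaf);
  P.min_split = std::max(2, min_split);
  return P;
}

}  // namespace

// [[Rcpp::export]]
List rf_train_cpp(NumericMatrix X, IntegerVector y, int n_trees, int max_depth,
                  int mtry, bool bootstrap, int min_leaf, int min_split,
                  int seed) {
  std::mt19937 rng((uint32_t)seed);
  RFParams P = make_params(n_trees, max_depth, mtry, bootstrap, min_leaf,
                           min_split);
  Forest F = train_forest(X, y, P, rng);
  return forest_to_list(F);
}

// [[Rcpp::export]]
NumericVector rf_predict_cpp(List forest, NumericMatrix X) {
  Forest F = forest_from_list(forest);
  const int n = X.nrow(), p = X.ncol();
  NumericVector out(n);
  std::vector<double> row(p);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < p; ++j) row[j] = X(i, j);
    out[i] = forest_prob_row(F, row.data());
  }
  return out;
}

// Leave-one-out predicted class-1 probability per row.
// [[Rcpp::export]]
NumericVector rf_loo_predict_cpp(NumericMatrix X, IntegerVector y, int n_trees,
                                 int max_depth, int mtry, bool bootstrap,
                                 int min_leaf, int min_split, int seed) {
  const int n = X.nrow(), p = X.ncol();
  RFParams P = make_params(n_trees, max_depth, mtry, bootstrap, min_leaf,
                           min_split);
  std::mt19937 master((uint32_t)seed);
  NumericVector out(n);
  NumericMatrix Xt(n - 1, p);
  IntegerVector yt(n - 1);
  std::vector<double> row(p);
  for (int i = 0; i < n; ++i) {
    int k = 0;
    for (int r = 0; r < n; ++r) {
      if (r == i) continue;
      for (int j = 0; j < p; ++j) Xt(k, j) = X(r, j);
      yt[k] = y[r];
      ++k;
    }
    std::mt19937 rng((uint32_t)master());
    Forest F = train_forest(Xt, yt, P, rng);
    for (int j = 0; j < p; ++j) row[j] = X(i, j);
    out[i] = forest_prob_row(F, row.data());
  }
  return out;
}

// Bootstrap x estimated-Shapley core: for each of B patient resamples
// (redrawn while single-class), retrain the forest and run R sampled
// permutations of the p elements, accumulating marginal contributions.
// A coalition is the set of INTACT elements: element intact -> feature 0,
// perturbed -> feature lesioned_values[j]. v is the class-1 probability or
// the hard class (hard = true). v(config) is memoised per bootstrap by the
// intact-set bitmask when p <= 64.
// [[Rcpp::export]]
List boot_shapley_cpp(NumericMatrix X, IntegerVector y, int n_trees,
                      int max_depth, int mtry, bool bootstrap, int min_leaf,
                      int min_split, int B, int R,
                      NumericVector lesioned_values, bool hard, int seed) {
  const int n = X.nrow(), p = X.ncol();
  if (lesioned_values.size() != p)
    stop("lesioned_values must have one entry per feature");
  RFParams P = make_params(n_trees, max_depth, mtry, bootstrap, min_leaf,
                           min_split);
  std::mt19937 master((uint32_t)seed);
  std::uniform_int_distribution<int> U(0, n - 1);

  NumericMatrix boot(B, p);
  int redraws = 0;
  NumericMatrix Xb(n, p);
  IntegerVector yb(n);
  std::vector<int> perm(p);
  std::vector<double> x(p), contrib(p);
  const bool use_cache = (p <= 64);

  for (int b = 0; b < B; ++b) {
    // resample patients with replacement; both classes must appear
    for (int attempt = 0;; ++attempt) {
      int n1 = 0;
      for (int i = 0; i < n; ++i) {
        int r = U(master);
        for (int j = 0; j < p; ++j) Xb(i, j) = X(r, j);
        yb[i] = y[r];
        n1 += y[r];
      }
      if (n1 > 0 && n1 < n) break;
      ++redraws;
      if (attempt > 10000)
        stop("could not draw a two-class bootstrap resample");
    }
    std::mt19937 rng((uint32_t)master());
    Forest F = train_forest(Xb, yb, P, rng);

    std::unordered_map<uint64_t, double> cache;
    auto value_of = [&](const double* xr, uint64_t key) {
      if (use_cache) {
        auto it = cache.find(key);
        if (it != cache.end()) return it->second;
      }
      double v = forest_prob_row(F, xr);
      if (hard) v = v >= 0.5 ? 1.0 : 0.0;
      if (use_cache) cache[key] = v;
      return v;
    };

    std::fill(contrib.begin(), contrib.end(), 0.0);
    for (int j = 0; j < p; ++j) perm[j] = j;
    for (int r = 0; r < R; ++r) {
      std::shuffle(perm.begin(), perm.end(), master);
      for (int j = 0; j < p; ++j) x[j] = lesioned_values[j];
      uint64_t key = 0;
      double v_prev = value_of(x.data(), key);
      for (int k = 0; k < p; ++k) {
        const int e = perm[k];
        x[e] = 0.0;
        if (use_cache && e < 64) key |= (uint64_t)1 << e;
        double v_new = value_of(x.data(), key);
        contrib[e] += v_new - v_prev;
        v_prev = v_new;
      }
    }
    for (int j = 0; j < p; ++j) boot(b, j) = contrib[j] / R;
  }
  return List::create(_["boot"] = boot, _["redraws"] = redraws);
}
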