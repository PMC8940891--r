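#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <random>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Deterministic RNG independent of R's stream: std::mt19937 output is
// standardized, so results are reproducible across platforms for a given
// seed. Modulo draws have negligible bias at the sizes used here.
struct Rng {
  std::mt19937 gen;
  explicit Rng(uint32_t seed) : gen(seed) {}
  int below(int n) { return static_cast<int>(gen() % static_cast<uint32_t>(n)); }
};

struct Node {
  int feat;       // -1 for leaf
  double thr;
  int left, right;
  double prob;    // class-1 fraction in node
};

static inline double gini_imp(int n1, int n) {
  if (n == 0) return 0.0;
  double p = static_cast<double>(n1) / n;
  return 2.0 * p * (1.0 - p);
}

struct TreeGrower {
  const double* Xp;           // column-major data
  const int* yp;
  int nrow, ncol;
  int mtry, min_node, n_root;
  Rng& rng;
  std::vector<Node>& nodes;
  std::vector<double>& imp;   // impurity-decrease accumulator per feature
  std::vector<int> feat_pool;
  std::vector<std::pair<double,int> > vals;  // (value, y) sort buffer

  TreeGrower(const NumericMatrix& X_, const IntegerVector& y_, int mtry_,
             int min_node_, Rng& rng_, std::vector<Node>& nodes_,
             std::vector<double>& imp_)
      : Xp(X_.begin()), yp(y_.begin()), nrow(X_.nrow()), ncol(X_.ncol()),
        mtry(mtry_), min_node(min_node_), n_root(0), rng(rng_),
        nodes(nodes_), imp(imp_) {
    feat_pool.resize(ncol);
    for (int j = 0; j < ncol; ++j) feat_pool[j] = j;
  }

  int grow(std::vector<int>& idx, int depth) {
    const int n = static_cast<int>(idx.size());
    int n1 = 0;
    for (int i = 0; i < n; ++i) n1 += yp[idx[i]];
    Node nd;
    nd.feat = -1; nd.thr = 0.0; nd.left = nd.right = -1;
    nd.prob = static_cast<double>(n1) / n;
    const int me = static_cast<int>(nodes.size());
    nodes.push_back(nd);
    if (n1 == 0 || n1 == n || n < 2 * min_node || depth > 40) return me;

    const double node_imp = gini_imp(n1, n);
    // sample mtry candidate features without replacement
    const int p = ncol;
    const int m = std::min(mtry, p);
    for (int i = 0; i < m; ++i) {
      int j = i + rng.below(p - i);
      std::swap(feat_pool[i], feat_pool[j]);
    }

    double best_dec = 1e-12;
    int best_f = -1;
    double best_thr = 0.0;
    for (int fi = 0; fi < m; ++fi) {
      const int f = feat_pool[fi];
      const double* col = Xp + static_cast<size_t>(f) * nrow;
      vals.resize(n);
      for (int i = 0; i < n; ++i) {
        vals[i].first = col[idx[i]];
        vals[i].second = yp[idx[i]];
      }
      std::sort(vals.begin(), vals.end());
      int left1 = 0;
      for (int i = 0; i < n - 1; ++i) {
        left1 += vals[i].second;
        if (vals[i].first == vals[i + 1].first) continue;
        const int nl = i + 1, nr = n - nl;
        if (nl < min_node || nr < min_node) continue;
        const double dec = node_imp -
          (nl * gini_imp(left1, nl) + nr * gini_imp(n1 - left1, nr)) / n;
        if (dec > best_dec) {
          best_dec = dec;
          best_f = f;
          best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
        }
      }
    }
    if (best_f < 0) return me;

    imp[best_f] += best_dec * n / n_root;
    std::vector<int> lidx, ridx;
    lidx.reserve(n); ridx.reserve(n);
    const double* bcol = Xp + static_cast<size_t>(best_f) * nrow;
    for (int i = 0; i < n; ++i) {
      if (bcol[idx[i]] <= best_thr) lidx.push_back(idx[i]);
      else ridx.push_back(idx[i]);
    }
    nodes[me].feat = best_f;
    nodes[me].thr = best_thr;
    const int l = grow(lidx, depth + 1);
    const int r = grow(ridx, depth + 1);
    nodes[me].left = l;
    nodes[me].right = r;
    return me;
  }
};

static void grow_forest(const NumericMatrix& X, const IntegerVector& y,
                        int ntree, int mtry, int min_node, uint32_t seed,
                        std::vector<std::vector<Node> >& trees,
                        std::vector<double>& imp) {
  const int n = X.nrow();
  imp.assign(X.ncol(), 0.0);
  Rng rng(seed);
  trees.resize(ntree);
  for (int t = 0; t < ntree; ++t) {
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = rng.below(n);  // bootstrap
    trees[t].clear();
    TreeGrower g(X, y, mtry, min_node, rng, trees[t], imp);
    g.n_root = n;
    g.grow(idx, 0);
  }
  for (size_t j = 0; j < imp.size(); ++j) imp[j] /= ntree;
}

static double predict_tree(const std::vector<Node>& nodes,
                           const NumericMatrix& X, int row) {
  int cur = 0;
  while (nodes[cur].feat >= 0)
    cur = (X(row, nodes[cur].feat) <= nodes[cur].thr) ? nodes[cur].left
                                                      : nodes[cur].right;
  return nodes[cur].prob;
}

// [[Rcpp::export]]
NumericVector rf_importance_cpp(NumericMatrix X, IntegerVector y, int ntree,
                                int mtry, int min_node, int seed) {
  std::vector<std::vector<Node> > trees;
  std::vector<double> imp;
  grow_forest(X, y, ntree, mtry, min_node, static_cast<uint32_t>(seed), trees,
              imp);
  return NumericVector(imp.begin(), imp.end());
}

// Train on (Xtrain, ytrain) and return per-row class-1 vote fractions on
// Xtest (each tree votes via its leaf majority; prob > 0.5 counts as 1).
// [[Rcpp::export]]
NumericVector rf_predict_cpp(NumericMatrix Xtrain, IntegerVector ytrain,
                             NumericMatrix Xtest, int ntree, int mtry,
                             int min_node, int seed) {
  std::vector<std::vector<Node> > trees;
  std::vector<double> imp;
  grow_forest(Xtrain, ytrain, ntree, mtry, min_node,
              static_cast<uint32_t>(seed), trees, imp);
  const int m = Xtest.nrow();
  NumericVector out(m);
  for (int i = 0; i < m; ++i) {
    int votes1 = 0;
    for (int t = 0; t < ntree; ++t)
      if (predict_tree(trees[t], Xtest, i) > 0.5) ++votes1;
    out[i] = static_cast<double>(votes1) / ntree;
  }
  return out;
}

// Permutation test for a one-term PERMANOVA. G is the Gower-centered inner
// product matrix (-1/2 C D^2 C), H the hat matrix of the model design.
// tr(H G) gives the among-group sum of squares; permuting sample identity
// permutes rows/cols of G.
// [[Rcpp::export]]
List permanova_perm_cpp(NumericMatrix G, NumericMatrix H, int df1, int df2,
                        int nperm, int seed) {
  const int n = G.nrow();
  double sst = 0.0;
  for (int i = 0; i < n; ++i) sst += G(i, i);
  double ssm = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) ssm += H(i, j) * G(i, j);
  // guard: with (numerically) zero residual SS the F ratio degenerates;
  // clamp the denominator so perfect separation yields a huge finite F
  const double floor_ss = 1e-12 * sst;
  const double res_obs = std::max(sst - ssm, floor_ss);
  const double f_obs = (ssm / df1) / (res_obs / df2);
  Rng rng(static_cast<uint32_t>(seed));
  std::vector<int> perm(n);
  int count_ge = 0;
  for (int b = 0; b < nperm; ++b) {
    for (int i = 0; i < n; ++i) perm[i] = i;
    for (int i = n - 1; i > 0; --i) {
      int j = rng.below(i + 1);
      std::swap(perm[i], perm[j]);
    }
    double ssm_p = 0.0;
    for (int i = 0; i < n; ++i) {
      const int pi = perm[i];
      for (int j = 0; j < n; ++j) ssm_p += H(i, j) * G(pi, perm[j]);
    }
    const double f_p = (ssm_p / df1) /
      (std::max(sst - ssm_p, floor_ss) / df2);
    if (f_p >= f_obs * (1.0 - 1e-12) - 1e-10) ++count_ge;
  }
  return List::create(_["f_obs"] = f_obs, _["r_squared"] = ssm / sst,
                      _["count_ge"] = count_ge);
}
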