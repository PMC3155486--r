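#include <Rcpp.h>
#include <vector>
#include <cmath>
#include "rng.h"

using namespace Rcpp;

// Classification trees with categorical predictors (small number of levels),
// splits = binary partitions of levels chosen to maximise the decrease in
// Bernoulli deviance. Variable subsampling is per tree; the in-bag sample is
// a stratified without-replacement subsample of inbag_per_class subjects per
// class. Importance of a variable is the total deviance decrease over all
// splits on it across all trees; the ensemble error is estimated from
// out-of-bag votes only.

namespace {

struct Tree {
  // node arrays; var = -1 marks a leaf
  std::vector<int> var, mask, left, right, vote, missdir; // missdir: 0 left, 1 right
};

inline double node_dev(int n1, int n) {
  if (n <= 0) return 0.0;
  const int n0 = n - n1;
  double d = 0.0;
  if (n1 > 0) d += n1 * std::log((double)n1 / n);
  if (n0 > 0) d += n0 * std::log((double)n0 / n);
  return -2.0 * d;
}

struct Grower {
  const IntegerMatrix& X;
  const IntegerVector& y;
  const IntegerVector& nlev;
  int min_node;
  Tree tree;
  std::vector<int> vars;      // candidate variables for this tree
  std::vector<double>* imp;   // importance accumulator (length P)

  Grower(const IntegerMatrix& X_, const IntegerVector& y_,
         const IntegerVector& nlev_, int min_node_, std::vector<double>* imp_)
    : X(X_), y(y_), nlev(nlev_), min_node(min_node_), imp(imp_) {}

  int new_node() {
    tree.var.push_back(-1); tree.mask.push_back(0);
    tree.left.push_back(-1); tree.right.push_back(-1);
    tree.vote.push_back(0); tree.missdir.push_back(0);
    return (int)tree.var.size() - 1;
  }

  // grow node for subject indices idx; returns node id
  int grow(std::vector<int>& idx) {
    const int node = new_node();
    const int n = (int)idx.size();
    int n1 = 0;
    for (int i : idx) n1 += y[i];
    tree.vote[node] = (2 * n1 > n) ? 1 : 0;
    if (n < min_node || n1 == 0 || n1 == n) return node;

    // best split over candidate vars / level partitions (non-missing only)
    double best_dec = 1e-12;
    int best_v = -1, best_mask = 0;
    for (int v : vars) {
      const int g = nlev[v];
      int cnt[8] = {0}, cnt1[8] = {0};
      int nm = 0, nm1 = 0;
      for (int i : idx) {
        const int x = X(i, v);
        if (x == NA_INTEGER) continue;
        cnt[x]++; cnt1[x] += y[i];
        nm++; nm1 += y[i];
      }
      if (nm < 2) continue;
      const double dparent = node_dev(nm1, nm);
      // binary partitions of {0..g-1}; level 0 kept on the left to skip
      // complements; mask must define two non-empty observed sides
      const int top = 1 << g;
      for (int mask = 1; mask < top - 1; mask += 2) {
        int nl = 0, nl1 = 0;
        for (int l = 0; l < g; ++l)
          if (mask >> l & 1) { nl += cnt[l]; nl1 += cnt1[l]; }
        const int nr = nm - nl, nr1 = nm1 - nl1;
        if (nl == 0 || nr == 0) continue;
        const double dec = dparent - node_dev(nl1, nl) - node_dev(nr1, nr);
        if (dec > best_dec) { best_dec = dec; best_v = v; best_mask = mask; }
      }
    }
    if (best_v < 0) return node;

    std::vector<int> lidx, ridx, midx;
    for (int i : idx) {
      const int x = X(i, best_v);
      if (x == NA_INTEGER) midx.push_back(i);
      else if (best_mask >> x & 1) lidx.push_back(i);
      else ridx.push_back(i);
    }
    const int missdir = (lidx.size() >= ridx.size()) ? 0 : 1;
    if (!midx.empty()) {
      std::vector<int>& tgt = missdir == 0 ? lidx : ridx;
      tgt.insert(tgt.end(), midx.begin(), midx.end());
    }
    tree.var[node] = best_v;
    tree.mask[node] = best_mask;
    tree.missdir[node] = missdir;
    (*imp)[best_v] += best_dec;
    const int l = grow(lidx);
    const int r = grow(ridx);
    tree.left[node] = l;
    tree.right[node] = r;
    return node;
  }
};

inline int tree_predict(const Tree& t, const IntegerMatrix& X, int row) {
  int node = 0;
  while (t.var[node] >= 0) {
    const int v = t.var[node];
    const int x = X(row, v);
    // unseen levels are recoded to NA by the caller; NA follows the more
    // populous child recorded at training time
    int go_left;
    if (x == NA_INTEGER || x < 0 || x >= 8) go_left = (t.missdir[node] == 0);
    else go_left = (t.mask[node] >> x) & 1;
    node = go_left ? t.left[node] : t.right[node];
  }
  return t.vote[node];
}

// partial Fisher-Yates: first k of a shuffle of 0..n-1
void sample_k(std::vector<int>& pool, int k, SplitMix64& rng, std::vector<int>& out) {
  const int n = (int)pool.size();
  for (int i = 0; i < k; ++i) {
    const int j = i + rng.bounded(n - i);
    std::swap(pool[i], pool[j]);
  }
  out.assign(pool.begin(), pool.begin() + k);
}

IntegerMatrix tree_to_matrix(const Tree& t) {
  const int m = (int)t.var.size();
  IntegerMatrix out(m, 6);
  for (int i = 0; i < m; ++i) {
    out(i, 0) = t.var[i]; out(i, 1) = t.mask[i];
    out(i, 2) = t.left[i]; out(i, 3) = t.right[i];
    out(i, 4) = t.vote[i]; out(i, 5) = t.missdir[i];
  }
  return out;
}

Tree matrix_to_tree(const IntegerMatrix& m) {
  Tree t;
  const int n = m.nrow();
  t.var.resize(n); t.mask.resize(n); t.left.resize(n);
  t.right.resize(n); t.vote.resize(n); t.missdir.resize(n);
  for (int i = 0; i < n; ++i) {
    t.var[i] = m(i, 0); t.mask[i] = m(i, 1); t.left[i] = m(i, 2);
    t.right[i] = m(i, 3); t.vote[i] = m(i, 4); t.missdir[i] = m(i, 5);
  }
  return t;
}

} // namespace

// [[Rcpp::export]]
List cpp_grow_forest(IntegerMatrix X, IntegerVector y, IntegerVector nlev,
                     int ntree, int mtry, int min_node, int inbag_per_class,
                     double seed, bool keep_trees, bool keep_inbag) {
  const int n = X.nrow(), P = X.ncol();
  std::vector<int> class0, class1;
  for (int i = 0; i < n; ++i) (y[i] == 1 ? class1 : class0).push_back(i);
  if (inbag_per_class < 1 ||
      inbag_per_class >= (int)class0.size() ||
      inbag_per_class >= (int)class1.size())
    stop("in-bag size per class must be >= 1 and < each class size");
  if (mtry < 1 || mtry > P) stop("mtry must be in [1, P]");

  std::vector<double> imp(P, 0.0);
  std::vector<int> votes1(n, 0), nvotes(n, 0);
  List trees(keep_trees ? ntree : 0);
  IntegerMatrix inbag_mat(keep_inbag ? ntree : 0, keep_inbag ? n : 0);
  const uint64_t master = (uint64_t)seed;

  std::vector<int> allvars(P);
  for (int j = 0; j < P; ++j) allvars[j] = j;

  for (int m = 0; m < ntree; ++m) {
    SplitMix64 rng(mix_seed(master, (uint64_t)m));
    // stratified in-bag, without replacement
    std::vector<int> p0(class0), p1(class1), ib0, ib1;
    sample_k(p0, inbag_per_class, rng, ib0);
    sample_k(p1, inbag_per_class, rng, ib1);
    std::vector<char> inbag(n, 0);
    std::vector<int> ib;
    ib.reserve(2 * inbag_per_class);
    for (int i : ib0) { inbag[i] = 1; ib.push_back(i); }
    for (int i : ib1) { inbag[i] = 1; ib.push_back(i); }

    Grower g(X, y, nlev, min_node, &imp);
    if (mtry == P) g.vars = allvars;
    else { std::vector<int> pool(allvars); sample_k(pool, mtry, rng, g.vars); }
    g.grow(ib);

    for (int i = 0; i < n; ++i) {
      if (inbag[i]) continue;
      votes1[i] += tree_predict(g.tree, X, i);
      nvotes[i]++;
    }
    if (keep_trees) trees[m] = tree_to_matrix(g.tree);
    if (keep_inbag)
      for (int i = 0; i < n; ++i) inbag_mat(m, i) = inbag[i];
  }

  // OOB error: majority vote per subject over trees where it was out-of-bag
  int nerr = 0, neval = 0;
  NumericVector oob_frac(n);
  for (int i = 0; i < n; ++i) {
    if (nvotes[i] == 0) { oob_frac[i] = NA_REAL; continue; }
    const double f = (double)votes1[i] / nvotes[i];
    oob_frac[i] = f;
    const int pred = f > 0.5 ? 1 : 0;
    neval++;
    if (pred != y[i]) nerr++;
  }
  const double lambda = neval > 0 ? (double)nerr / neval : NA_REAL;

  List out = List::create(
    _["importance"] = NumericVector(imp.begin(), imp.end()),
    _["oob_votes"] = oob_frac,
    _["oob_n"] = IntegerVector(nvotes.begin(), nvotes.end()),
    _["oob_error"] = lambda);
  if (keep_trees) out["trees"] = trees;
  if (keep_inbag) out["inbag"] = inbag_mat;
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_predict_forest(List trees, IntegerMatrix X) {
  const int n = X.nrow(), M = trees.size();
  NumericVector out(n);
  std::vector<Tree> ts;
  ts.reserve(M);
  for (int m = 0; m < M; ++m) ts.push_back(matrix_to_tree(trees[m]));
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int m = 0; m < M; ++m) s += tree_predict(ts[m], X, i);
    out[i] = s / M;
  }
  return out;
}
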