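// Exact per-class SHAP values for ranger probability forests.
//
// For each tree we compute the path-dependent conditional expectation
// v(S): descend the tree; at a split on a feature in S follow the data,
// otherwise average the two children weighted by their in-bag cover.
// SHAP values are the exact Shapley values of v over the features the
// tree actually uses (features unused by a tree have zero attribution),
// obtained by direct enumeration of feature subsets. Trees here are
// shallow (a handful of splits), so enumeration is exact and cheap.
// Forest values are the average over trees; local accuracy
// (base + sum(phi) = predicted class probability) holds by construction.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

namespace {

struct Tree {
  std::vector<int> left, right, splitvar;
  std::vector<double> splitval, cover;
  std::vector<std::vector<double>> leaf;  // empty for internal nodes
  std::vector<int> used;                  // distinct feature ids
  std::vector<int> bit;                   // feature id -> bit index or -1
};

bool is_leaf(const Tree& t, int node) { return !t.leaf[node].empty(); }

void add_cover(Tree& t, const NumericMatrix& xtrain, int row, double w) {
  int node = 0;
  for (;;) {
    t.cover[node] += w;
    if (is_leaf(t, node)) return;
    node = xtrain(row, t.splitvar[node]) <= t.splitval[node]
               ? t.left[node] : t.right[node];
  }
}

// Accumulate w * E[f | S] into out, descending from `node`.
void walk(const Tree& t, int node, double w, const std::vector<double>& x,
          unsigned int mask, int nclass, std::vector<double>& out) {
  if (is_leaf(t, node)) {
    const std::vector<double>& lv = t.leaf[node];
    for (int c = 0; c < nclass; ++c) out[c] += w * lv[c];
    return;
  }
  int f = t.splitvar[node];
  int b = t.bit[f];
  if ((mask >> b) & 1u) {
    int nxt = x[f] <= t.splitval[node] ? t.left[node] : t.right[node];
    walk(t, nxt, w, x, mask, nclass, out);
  } else {
    double cl = t.cover[t.left[node]], cr = t.cover[t.right[node]];
    double tot = cl + cr;
    if (tot <= 0) { cl = 0.5; cr = 0.5; tot = 1.0; }
    walk(t, t.left[node], w * cl / tot, x, mask, nclass, out);
    walk(t, t.right[node], w * cr / tot, x, mask, nclass, out);
  }
}

}  // namespace

// [[Rcpp::export]]
List treeshap_forest_cpp(List left, List right, List splitvar, List splitval,
                         List termcounts, List inbag, NumericMatrix xtrain,
                         NumericMatrix xtest) {
  const int ntrees = left.size();
  const int nfeat = xtrain.ncol();
  const int ntest = xtest.nrow();
  if (ntrees == 0) stop("Empty forest.");

  // number of classes from the first terminal node found
  int nclass = -1;
  {
    List tc0 = termcounts[0];
    for (int j = 0; j < tc0.size() && nclass < 0; ++j) {
      NumericVector v = tc0[j];
      if (v.size() > 0) nclass = v.size();
    }
  }
  if (nclass < 1) stop("Could not determine class count from forest.");

  // factorial table for Shapley weights
  std::vector<double> fact(32, 1.0);
  for (int i = 1; i < 32; ++i) fact[i] = fact[i - 1] * i;

  std::vector<double> shap((size_t)ntest * nfeat * nclass, 0.0);
  std::vector<double> base(nclass, 0.0);
  std::vector<double> pred((size_t)ntest * nclass, 0.0);

  for (int ti = 0; ti < ntrees; ++ti) {
    NumericVector L = left[ti], R = right[ti], SV = splitvar[ti],
                  SP = splitval[ti], IB = inbag[ti];
    List TC = termcounts[ti];
    const int nn = L.size();

    Tree t;
    t.left.resize(nn); t.right.resize(nn);
    t.splitvar.resize(nn); t.splitval.resize(nn);
    t.cover.assign(nn, 0.0); t.leaf.assign(nn, {});
    t.bit.assign(nfeat, -1);
    for (int j = 0; j < nn; ++j) {
      t.left[j] = (int)L[j]; t.right[j] = (int)R[j];
      t.splitvar[j] = (int)SV[j]; t.splitval[j] = SP[j];
      NumericVector v = TC[j];
      if (v.size() > 0) t.leaf[j] = as<std::vector<double>>(v);
    }
    for (int j = 0; j < nn; ++j) {
      if (!is_leaf(t, j)) {
        int f = t.splitvar[j];
        if (f < 0 || f >= nfeat) stop("Split variable out of range.");
        if (t.bit[f] < 0) { t.bit[f] = t.used.size(); t.used.push_back(f); }
      }
    }
    const int k = t.used.size();
    if (k > 25) stop("A tree uses more than 25 features; enumeration refused.");

    if ((int)IB.size() != xtrain.nrow()) stop("In-bag length mismatch.");
    for (int r = 0; r < xtrain.nrow(); ++r) {
      if (IB[r] > 0) add_cover(t, xtrain, r, IB[r]);
    }

    const unsigned int nsub = 1u << k;
    std::vector<std::vector<double>> vs(nsub,
                                        std::vector<double>(nclass, 0.0));
    std::vector<double> xrow(nfeat);

    for (int s = 0; s < ntest; ++s) {
      for (int f = 0; f < nfeat; ++f) xrow[f] = xtest(s, f);
      for (unsigned int m = 0; m < nsub; ++m) {
        std::fill(vs[m].begin(), vs[m].end(), 0.0);
        walk(t, 0, 1.0, xrow, m, nclass, vs[m]);
      }
      for (int c = 0; c < nclass; ++c) {
        if (s == 0) base[c] += vs[0][c];
        pred[(size_t)s * nclass + c] += vs[nsub - 1][c];
      }
      for (int i = 0; i < k; ++i) {
        const unsigned int ibit = 1u << i;
        const int f = t.used[i];
        for (unsigned int m = 0; m < nsub; ++m) {
          if (m & ibit) continue;
          int sz = __builtin_popcount(m);
          double w = fact[sz] * fact[k - sz - 1] / fact[k];
          for (int c = 0; c < nclass; ++c) {
            shap[((size_t)s * nfeat + f) * nclass + c] +=
                w * (vs[m | ibit][c] - vs[m][c]);
          }
        }
      }
    }
  }

  for (auto& v : base) v /= ntrees;
  NumericMatrix pred_out(nclass, ntest);
  for (int s = 0; s < ntest; ++s)
    for (int c = 0; c < nclass; ++c)
      pred_out(c, s) = pred[(size_t)s * nclass + c] / ntrees;
  for (auto& v : shap) v /= ntrees;
  NumericVector shap_scaled(shap.begin(), shap.end());
  shap_scaled.attr("dim") = IntegerVector::create(nclass, nfeat, ntest);

  return List::create(_["shap"] = shap_scaled,
                      _["base"] = NumericVector(base.begin(), base.end()),
                      _["pred"] = pred_out);
}
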