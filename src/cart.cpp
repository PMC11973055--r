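#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Greedy binary CART for two classes, gini impurity, exhaustive split
// search, sample weights. Sized for very wide, very short design matrices
// (formula-based tree engines choke on thousands of columns).

namespace {

struct Node {
  int feat = -1;
  double thr = 0.0;
  double p1 = 0.5;   // weighted class-1 fraction (leaf payload)
  int left = -1, right = -1;
};

struct Builder {
  const NumericMatrix& X;
  const IntegerVector& y;
  const NumericVector& w;
  int max_depth;
  double min_weight = 1e-12;
  std::vector<Node> nodes;

  Builder(const NumericMatrix& X_, const IntegerVector& y_,
          const NumericVector& w_, int depth_)
      : X(X_), y(y_), w(w_), max_depth(depth_) {}

  int build(std::vector<int>& idx, int depth) {
    Node node;
    double w1 = 0.0, wt = 0.0;
    for (int i : idx) { wt += w[i]; if (y[i] == 1) w1 += w[i]; }
    node.p1 = wt > 0 ? w1 / wt : 0.5;
    const bool pure = (w1 < min_weight) || (wt - w1 < min_weight);
    if (pure || (int)idx.size() < 2 || depth >= max_depth) {
      nodes.push_back(node);
      return (int)nodes.size() - 1;
    }
    // exhaustive best split: minimize weighted gini of the children
    int best_feat = -1;
    double best_thr = 0.0, best_imp = R_PosInf;
    const int p = X.ncol();
    std::vector<int> ord(idx);
    for (int j = 0; j < p; ++j) {
      std::sort(ord.begin(), ord.end(),
                [&](int a, int b) { return X(a, j) < X(b, j); });
      double wl = 0.0, wl1 = 0.0;
      for (size_t k = 0; k + 1 < ord.size(); ++k) {
        const int i = ord[k];
        wl += w[i];
        if (y[i] == 1) wl1 += w[i];
        const double xl = X(i, j), xr = X(ord[k + 1], j);
        if (xr <= xl) continue;  // no gap, not a valid threshold
        const double wr = wt - wl, wr1 = w1 - wl1;
        if (wl < min_weight || wr < min_weight) continue;
        const double gl = 1.0 - ((wl1 / wl) * (wl1 / wl) +
                                 ((wl - wl1) / wl) * ((wl - wl1) / wl));
        const double gr = 1.0 - ((wr1 / wr) * (wr1 / wr) +
                                 ((wr - wr1) / wr) * ((wr - wr1) / wr));
        const double imp = wl * gl + wr * gr;
        if (imp < best_imp - 1e-15) {
          best_imp = imp;
          best_feat = j;
          best_thr = 0.5 * (xl + xr);
        }
      }
    }
    if (best_feat < 0) {  // all candidate features constant on this node
      nodes.push_back(node);
      return (int)nodes.size() - 1;
    }
    std::vector<int> li, ri;
    for (int i : idx) {
      if (X(i, best_feat) <= best_thr) li.push_back(i); else ri.push_back(i);
    }
    node.feat = best_feat;
    node.thr = best_thr;
    nodes.push_back(node);
    const int me = (int)nodes.size() - 1;
    const int l = build(li, depth + 1);
    const int r = build(ri, depth + 1);
    nodes[me].left = l;
    nodes[me].right = r;
    return me;
  }

  double predict_row(const NumericMatrix& M, int row) const {
    int cur = 0;
    while (nodes[cur].feat >= 0) {
      cur = (M(row, nodes[cur].feat) <= nodes[cur].thr)
                ? nodes[cur].left : nodes[cur].right;
    }
    return nodes[cur].p1;
  }
};

}  // namespace

// Fit on (Xtr, ytr, w) and return class-1 probabilities for Xte and Xtr.
// [[Rcpp::export(name = ".cart_fit_predict")]]
List cart_fit_predict(NumericMatrix Xtr, IntegerVector ytr, NumericVector w,
                      NumericMatrix Xte, int max_depth) {
  if (Xtr.nrow() != ytr.size() || Xtr.nrow() != w.size()) {
    stop("row/label/weight length mismatch");
  }
  Builder b(Xtr, ytr, w, max_depth);
  std::vector<int> idx(Xtr.nrow());
  for (int i = 0; i < Xtr.nrow(); ++i) idx[i] = i;
  b.build(idx, 0);
  NumericVector pte(Xte.nrow()), ptr_(Xtr.nrow());
  for (int i = 0; i < Xte.nrow(); ++i) pte[i] = b.predict_row(Xte, i);
  for (int i = 0; i < Xtr.nrow(); ++i) ptr_[i] = b.predict_row(Xtr, i);
  return List::create(_["test_p1"] = pte, _["train_p1"] = ptr_);
}
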