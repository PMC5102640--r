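#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Binary CART (Gini impurity, grown to purity) for two-class problems with
// native missing-value handling: at each split, rows with a missing value on
// the split feature are routed to the child that minimises the weighted Gini
// impurity; the learned direction is stored and followed at prediction time.
// Ties between candidate splits break deterministically on the lowest feature
// index, then the lowest threshold.

namespace {

struct Node {
  int feature;        // -1 for leaf
  double threshold;   // x <= threshold goes left
  int missing_left;   // 1: missing goes left, 0: right
  int left, right;    // child indices, -1 for leaf
  double pos_frac;    // positive-class fraction of training rows in node
};

struct Problem {
  const double* X;    // column-major n x p
  const int* y;       // 0/1
  int n, p;
};

double gini_counts(double n1, double n0) {
  double n = n1 + n0;
  if (n <= 0.0) return 0.0;
  double p1 = n1 / n, p0 = n0 / n;
  return 1.0 - p1 * p1 - p0 * p0;
}

struct Split {
  bool found = false;
  int feature = -1;
  double threshold = 0.0;
  bool missing_left = true;
  double score = R_PosInf;  // weighted child impurity (lower is better)
};

Split best_split(const Problem& pb, const std::vector<int>& rows) {
  Split best;
  int n = (int)rows.size();
  std::vector<std::pair<double, int>> vals;
  vals.reserve(n);
  for (int j = 0; j < pb.p; ++j) {
    const double* xj = pb.X + (size_t)j * pb.n;
    vals.clear();
    double miss_pos = 0, miss_neg = 0;
    double tot_pos = 0, tot_neg = 0;
    for (int r : rows) {
      double v = xj[r];
      int yi = pb.y[r];
      if (ISNAN(v)) {
        if (yi) miss_pos++; else miss_neg++;
      } else {
        vals.push_back(std::make_pair(v, yi));
        if (yi) tot_pos++; else tot_neg++;
      }
    }
    if (vals.size() < 2) continue;
    std::sort(vals.begin(), vals.end());
    double left_pos = 0, left_neg = 0;
    for (size_t k = 0; k + 1 < vals.size(); ++k) {
      if (vals[k].second) left_pos++; else left_neg++;
      if (vals[k].first == vals[k + 1].first) continue;  // no cut inside ties
      double thr = vals[k].first + 0.5 * (vals[k + 1].first - vals[k].first);
      double right_pos = tot_pos - left_pos, right_neg = tot_neg - left_neg;
      // route missing rows to whichever side gives lower weighted impurity
      for (int ml = 1; ml >= 0; --ml) {
        double lp = left_pos + (ml ? miss_pos : 0.0);
        double ln = left_neg + (ml ? miss_neg : 0.0);
        double rp = right_pos + (ml ? 0.0 : miss_pos);
        double rn = right_neg + (ml ? 0.0 : miss_neg);
        double nl = lp + ln, nr = rp + rn;
        double score = (nl * gini_counts(lp, ln) + nr * gini_counts(rp, rn)) / n;
        bool better = score < best.score - 1e-12;
        if (better) {
          best.found = true;
          best.feature = j;
          best.threshold = thr;
          best.missing_left = (ml == 1);
          best.score = score;
        }
      }
    }
  }
  return best;
}

void grow(const Problem& pb, std::vector<Node>& tree, int node_idx,
          const std::vector<int>& rows, int depth, int max_depth) {
  double pos = 0;
  for (int r : rows) pos += pb.y[r];
  int n = (int)rows.size();
  tree[node_idx].pos_frac = n ? pos / n : 0.5;
  tree[node_idx].feature = -1;
  tree[node_idx].left = tree[node_idx].right = -1;
  bool pure = (pos == 0 || pos == n);
  if (pure || n < 2 || (max_depth > 0 && depth >= max_depth)) return;
  Split sp = best_split(pb, rows);
  if (!sp.found) return;
  // a split must actually partition the rows
  std::vector<int> lrows, rrows;
  const double* xj = pb.X + (size_t)sp.feature * pb.n;
  for (int r : rows) {
    double v = xj[r];
    bool go_left = ISNAN(v) ? sp.missing_left : (v <= sp.threshold);
    if (go_left) lrows.push_back(r); else rrows.push_back(r);
  }
  if (lrows.empty() || rrows.empty()) return;
  tree[node_idx].feature = sp.feature;
  tree[node_idx].threshold = sp.threshold;
  tree[node_idx].missing_left = sp.missing_left ? 1 : 0;
  tree.push_back(Node());
  int li = (int)tree.size() - 1;
  tree.push_back(Node());
  int ri = (int)tree.size() - 1;
  tree[node_idx].left = li;
  tree[node_idx].right = ri;
  grow(pb, tree, li, lrows, depth + 1, max_depth);
  grow(pb, tree, ri, rrows, depth + 1, max_depth);
}

}  // namespace

// [[Rcpp::export]]
List cart_fit(NumericMatrix X, IntegerVector y, int max_depth = 0) {
  int n = X.nrow(), p = X.ncol();
  if (n != y.size()) stop("X and y dimensions disagree");
  Problem pb{REAL(X), INTEGER(y), n, p};
  std::vector<Node> tree;
  tree.push_back(Node());
  std::vector<int> rows(n);
  for (int i = 0; i < n; ++i) rows[i] = i;
  grow(pb, tree, 0, rows, 0, max_depth);
  int m = (int)tree.size();
  IntegerVector feature(m), mleft(m), left(m), right(m);
  NumericVector threshold(m), pos_frac(m);
  for (int i = 0; i < m; ++i) {
    feature[i] = tree[i].feature;
    threshold[i] = tree[i].threshold;
    mleft[i] = tree[i].missing_left;
    left[i] = tree[i].left;
    right[i] = tree[i].right;
    pos_frac[i] = tree[i].pos_frac;
  }
  return List::create(_["feature"] = feature, _["threshold"] = threshold,
                      _["missing_left"] = mleft, _["left"] = left,
                      _["right"] = right, _["pos_frac"] = pos_frac);
}

// [[Rcpp::export]]
NumericVector cart_score(List tree, NumericMatrix X) {
  IntegerVector feature = tree["feature"], left = tree["left"],
                right = tree["right"], mleft = tree["missing_left"];
  NumericVector threshold = tree["threshold"], pos_frac = tree["pos_frac"];
  int n = X.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (feature[node] >= 0) {
      double v = X(i, feature[node]);
      bool go_left = ISNAN(v) ? (mleft[node] == 1) : (v <= threshold[node]);
      node = go_left ? left[node] : right[node];
    }
    out[i] = pos_frac[node];
  }
  return out;
}

// Cascaded-biquad IIR filtering (direct form II transposed) with explicit
// initial section states; states enter scaled by x[0] so a constant input
// passes through a unit-DC-gain cascade without a start-up transient.
// sos: k x 6 matrix, rows (b0, b1, b2, 1, a1, a2).
// [[Rcpp::export]]
NumericVector sos_filter(NumericMatrix sos, NumericVector x, NumericMatrix zi) {
  int k = sos.nrow(), n = x.size();
  if (zi.nrow() != k || zi.ncol() != 2) stop("zi must be k x 2");
  NumericVector y = clone(x);
  for (int s = 0; s < k; ++s) {
    double b0 = sos(s, 0), b1 = sos(s, 1), b2 = sos(s, 2);
    double a1 = sos(s, 4), a2 = sos(s, 5);
    double s1 = zi(s, 0), s2 = zi(s, 1);
    for (int t = 0; t < n; ++t) {
      double xt = y[t];
      double yt = b0 * xt + s1;
      s1 = b1 * xt - a1 * yt + s2;
      s2 = b2 * xt - a2 * yt;
      y[t] = yt;
    }
  }
  return y;
}
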