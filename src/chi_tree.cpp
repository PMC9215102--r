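#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Pearson chi-square statistic (no continuity correction) of the 2x2 table
//   rows: split side (left = value <= threshold, right = value > threshold)
//   cols: label (case / control)
// Returns 0 when any margin is 0.
static inline double chi2_2x2(double a, double b, double c, double d) {
  const double n  = a + b + c + d;
  const double r1 = a + b, r2 = c + d, c1 = a + c, c2 = b + d;
  if (r1 <= 0.0 || r2 <= 0.0 || c1 <= 0.0 || c2 <= 0.0) return 0.0;
  const double det = a * d - b * c;
  return n * det * det / (r1 * r2 * c1 * c2);
}

namespace {

struct NodeRec {
  int depth;        // root = 1
  int feat;         // 1-based column of X, 0 for leaf
  double threshold;
  double chisq;     // statistic of the chosen split, 0 for leaf
  int n;
  int n_case;
  int left;         // 1-based node index, 0 for leaf
  int right;
};

struct TreeCtx {
  const double* X;  // column-major n x p
  const int* y;
  int n, p;
  std::vector<int> feats;          // 0-based candidate columns, ascending
  int min_node, max_depth;
  std::vector<NodeRec>* nodes;     // optional node log
  double* imp;                     // optional importance accumulator
};

// Recursive growth on per-feature presorted index lists. lists[k] holds the
// node's sample indices sorted by feature feats[k]; partitioning preserves
// order, so no sorting happens below the root. Split choice: the (feature,
// midpoint-threshold) pair maximising the chi-square statistic, ties broken
// by smaller feature column then smaller threshold (features are scanned in
// ascending column order, thresholds ascending, strict improvement).
int grow_node(TreeCtx& C, std::vector<std::vector<int> >& lists, int depth) {
  const int m = (int)lists[0].size();
  int n1 = 0;
  for (int i = 0; i < m; ++i) n1 += C.y[lists[0][i]];

  int me = 0;
  if (C.nodes) {
    NodeRec rec;
    rec.depth = depth; rec.feat = 0; rec.threshold = NA_REAL; rec.chisq = 0.0;
    rec.n = m; rec.n_case = n1; rec.left = 0; rec.right = 0;
    C.nodes->push_back(rec);
    me = (int)C.nodes->size();
  }

  const bool pure = (n1 == 0 || n1 == m);
  const bool too_small = m < C.min_node;
  const bool too_deep = (C.max_depth > 0 && depth >= C.max_depth);
  if (pure || too_small || too_deep) return me;

  int best_k = -1;
  double best_thr = 0.0, best_chi = 0.0;
  const double tot1 = (double)n1, tot0 = (double)(m - n1);
  for (size_t k = 0; k < C.feats.size(); ++k) {
    const double* col = C.X + (size_t)C.feats[k] * C.n;
    const std::vector<int>& ord = lists[k];
    double l1 = 0.0, l0 = 0.0;
    for (int i = 0; i < m - 1; ++i) {
      if (C.y[ord[i]] == 1) l1 += 1.0; else l0 += 1.0;
      const double v = col[ord[i]], vn = col[ord[i + 1]];
      if (v < vn) {
        const double stat = chi2_2x2(l1, l0, tot1 - l1, tot0 - l0);
        if (stat > best_chi) {
          best_chi = stat;
          best_k = (int)k;
          best_thr = v + (vn - v) / 2.0;
        }
      }
    }
  }
  if (best_k < 0 || best_chi <= 0.0) return me;

  const int bf = C.feats[best_k];
  const double* bcol = C.X + (size_t)bf * C.n;
  if (C.imp) C.imp[bf] += std::ldexp(best_chi, -depth);   // 2^(-L) * G
  if (C.nodes) {
    (*C.nodes)[me - 1].feat = bf + 1;
    (*C.nodes)[me - 1].threshold = best_thr;
    (*C.nodes)[me - 1].chisq = best_chi;
  }

  // order-preserving partition of every feature's index list
  std::vector<std::vector<int> > left(C.feats.size()), right(C.feats.size());
  for (size_t k = 0; k < C.feats.size(); ++k) {
    const std::vector<int>& ord = lists[k];
    left[k].reserve(m); right[k].reserve(m);
    for (int i = 0; i < m; ++i) {
      if (bcol[ord[i]] <= best_thr) left[k].push_back(ord[i]);
      else right[k].push_back(ord[i]);
    }
    std::vector<int>().swap(lists[k]);  // free as we go
  }
  const int lch = grow_node(C, left, depth + 1);
  std::vector<std::vector<int> >().swap(left);
  const int rch = grow_node(C, right, depth + 1);
  if (C.nodes) {
    (*C.nodes)[me - 1].left = lch;
    (*C.nodes)[me - 1].right = rch;
  }
  return me;
}

void sort_column(const double* col, int n, std::vector<int>& ord) {
  ord.resize(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(),
                   [col](int a, int b) { return col[a] < col[b]; });
}

void grow_tree(TreeCtx& C, const std::vector<std::vector<int> >& presort) {
  std::vector<std::vector<int> > lists(C.feats.size());
  for (size_t k = 0; k < C.feats.size(); ++k) lists[k] = presort[C.feats[k]];
  grow_node(C, lists, 1);
}

NumericMatrix nodes_to_matrix(const std::vector<NodeRec>& nodes) {
  NumericMatrix out((int)nodes.size(), 8);
  for (size_t i = 0; i < nodes.size(); ++i) {
    out(i, 0) = nodes[i].depth;
    out(i, 1) = nodes[i].feat == 0 ? NA_REAL : nodes[i].feat;
    out(i, 2) = nodes[i].threshold;
    out(i, 3) = nodes[i].chisq;
    out(i, 4) = nodes[i].n;
    out(i, 5) = nodes[i].n_case;
    out(i, 6) = nodes[i].left == 0 ? NA_REAL : nodes[i].left;
    out(i, 7) = nodes[i].right == 0 ? NA_REAL : nodes[i].right;
  }
  colnames(out) = CharacterVector::create("depth", "split_col", "threshold",
                                          "chi_square", "n_samples", "n_case",
                                          "left", "right");
  return out;
}

void check_inputs(const NumericMatrix& X, const IntegerVector& y) {
  if (y.size() != X.nrow()) stop("labels must match rows of the feature matrix");
  int n1 = 0;
  for (int i = 0; i < y.size(); ++i) {
    if (y[i] != 0 && y[i] != 1) stop("labels must be 0/1");
    n1 += y[i];
  }
  if (n1 == 0 || n1 == y.size())
    stop("labels must contain both classes at the root");
}

std::vector<int> check_feats(const IntegerVector& feats, int p) {
  if (feats.size() == 0) stop("empty feature subset");
  std::vector<int> fv;
  fv.reserve(feats.size());
  for (int i = 0; i < feats.size(); ++i) {
    if (feats[i] == NA_INTEGER) continue;   // ragged subsets padded with NA
    if (feats[i] < 1 || feats[i] > p) stop("feature index out of range");
    fv.push_back(feats[i] - 1);
  }
  if (fv.empty()) stop("empty feature subset");
  std::sort(fv.begin(), fv.end());
  return fv;
}

} // namespace

// [[Rcpp::export]]
double cpp_chi_square(double left_case, double left_ctrl,
                      double right_case, double right_ctrl) {
  if (left_case < 0 || left_ctrl < 0 || right_case < 0 || right_ctrl < 0)
    stop("counts must be non-negative");
  if (left_case + left_ctrl + right_case + right_ctrl < 1)
    stop("total count must be at least 1");
  return chi2_2x2(left_case, left_ctrl, right_case, right_ctrl);
}

// [[Rcpp::export]]
NumericMatrix cpp_grow_tree(NumericMatrix X, IntegerVector y,
                            IntegerVector feats, int min_node, int max_depth) {
  check_inputs(X, y);
  const int n = X.nrow(), p = X.ncol();
  std::vector<NodeRec> nodes;
  TreeCtx C{ REAL(X), INTEGER(y), n, p, check_feats(feats, p),
             min_node, max_depth, &nodes, (double*)0 };
  std::vector<std::vector<int> > presort(p);
  for (size_t k = 0; k < C.feats.size(); ++k)
    sort_column(C.X + (size_t)C.feats[k] * n, n, presort[C.feats[k]]);
  grow_tree(C, presort);
  return nodes_to_matrix(nodes);
}

// [[Rcpp::export]]
NumericVector cpp_forest_importance(NumericMatrix X, IntegerVector y,
                                    IntegerMatrix subsets, int min_node,
                                    int max_depth) {
  check_inputs(X, y);
  const int n = X.nrow(), p = X.ncol();
  const int n_trees = subsets.nrow();
  if (n_trees < 1) stop("need at least one tree");

  // presort every column once; trees reuse the shared orderings
  std::vector<std::vector<int> > presort(p);
  std::vector<bool> sorted(p, false);

  NumericVector imp(p);
  for (int t = 0; t < n_trees; ++t) {
    IntegerVector row = subsets(t, _);
    TreeCtx C{ REAL(X), INTEGER(y), n, p, check_feats(row, p),
               min_node, max_depth, (std::vector<NodeRec>*)0, REAL(imp) };
    for (size_t k = 0; k < C.feats.size(); ++k) {
      const int f = C.feats[k];
      if (!sorted[f]) { sort_column(C.X + (size_t)f * n, n, presort[f]); sorted[f] = true; }
    }
    grow_tree(C, presort);
  }
  for (int j = 0; j < p; ++j) imp[j] /= (double)n_trees;
  return imp;
}
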