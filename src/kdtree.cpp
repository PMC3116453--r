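// Balanced k-d tree over 2-D (planar) or 3-D (unit-sphere embedded lon/lat)
// points, with k-nearest queries. Ties in squared distance are broken by the
// smaller point index, so results are deterministic and match a brute-force
// scan ordered by (distance, index).
#include <Rcpp.h>
#include <algorithm>
#include <queue>
#include <vector>
using namespace Rcpp;

struct KDTree {
  std::vector<double> pts; // row-major, n x dim
  std::vector<int> order;  // tree layout: indices into pts
  int n, dim;

  double coord(int i, int d) const { return pts[i * dim + d]; }

  void build(int lo, int hi, int depth) {
    if (hi - lo <= 1) return;
    int axis = depth % dim;
    int mid = lo + (hi - lo) / 2;
    std::nth_element(order.begin() + lo, order.begin() + mid,
                     order.begin() + hi, [&](int a, int b) {
                       double ca = coord(a, axis), cb = coord(b, axis);
                       if (ca != cb) return ca < cb;
                       return a < b;
                     });
    build(lo, mid, depth + 1);
    build(mid + 1, hi, depth + 1);
  }

  typedef std::pair<double, int> Cand; // (squared distance, point index)

  void query(const double* q, int k, int lo, int hi, int depth,
             std::priority_queue<Cand>& heap) const {
    if (lo >= hi) return;
    int axis = depth % dim;
    int mid = lo + (hi - lo) / 2;
    int idx = order[mid];
    double d2 = 0.0;
    for (int d = 0; d < dim; ++d) {
      double diff = q[d] - coord(idx, d);
      d2 += diff * diff;
    }
    Cand cand(d2, idx);
    if ((int)heap.size() < k) {
      heap.push(cand);
    } else if (cand < heap.top()) {
      heap.pop();
      heap.push(cand);
    }
    double split = q[axis] - coord(idx, axis);
    int nearLo = lo, nearHi = mid, farLo = mid + 1, farHi = hi;
    if (split > 0) { nearLo = mid + 1; nearHi = hi; farLo = lo; farHi = mid; }
    query(q, k, nearLo, nearHi, depth + 1, heap);
    // the far half can still hold an equal-distance, smaller-index point,
    // so recurse on <= rather than <
    if ((int)heap.size() < k || split * split <= heap.top().first)
      query(q, k, farLo, farHi, depth + 1, heap);
  }
};

// [[Rcpp::export(name = ".kdtree_build")]]
SEXP kdtree_build(NumericMatrix points) {
  XPtr<KDTree> tree(new KDTree(), true);
  tree->n = points.nrow();
  tree->dim = points.ncol();
  if (tree->n < 1) stop("k-d tree requires at least one point");
  tree->pts.resize((size_t)tree->n * tree->dim);
  for (int i = 0; i < tree->n; ++i)
    for (int d = 0; d < tree->dim; ++d)
      tree->pts[(size_t)i * tree->dim + d] = points(i, d);
  tree->order.resize(tree->n);
  for (int i = 0; i < tree->n; ++i) tree->order[i] = i;
  tree->build(0, tree->n, 0);
  return tree;
}

// [[Rcpp::export(name = ".kdtree_query")]]
List kdtree_query(SEXP treePtr, NumericMatrix queries, int k) {
  XPtr<KDTree> tree(treePtr);
  if (queries.ncol() != tree->dim) stop("query dimension mismatch");
  int nq = queries.nrow();
  int kk = std::min(k, tree->n);
  IntegerMatrix idx(nq, kk);
  NumericMatrix d2(nq, kk);
  std::vector<double> q(tree->dim);
  for (int i = 0; i < nq; ++i) {
    for (int d = 0; d < tree->dim; ++d) q[d] = queries(i, d);
    std::priority_queue<KDTree::Cand> heap;
    tree->query(q.data(), kk, 0, tree->n, 0, heap);
    for (int j = kk - 1; j >= 0; --j) {
      idx(i, j) = heap.top().second + 1; // 1-based for R
      d2(i, j) = heap.top().first;
      heap.pop();
    }
  }
  return List::create(_["idx"] = idx, _["dist2"] = d2);
}
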