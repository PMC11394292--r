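// Dimension-general kd-tree used for all nearest-neighbour queries:
// k-NN distances (statistical outlier removal), radius counts (density
// condition), closest-point search (ICP) and descriptor matching.
#include <Rcpp.h>
#include <algorithm>
#include <queue>
#include <vector>
#include <cmath>

namespace {

struct Node {
  int start, end;       // range in the index permutation
  int axis;             // split axis, -1 for leaf
  double split;         // split coordinate
  int left, right;      // child node ids, -1 for leaf
};

class KDTree {
public:
  KDTree(const Rcpp::NumericMatrix& pts, int leaf_size = 16)
      : pts_(pts), n_(pts.nrow()), dim_(pts.ncol()), leaf_(leaf_size) {
    idx_.resize(n_);
    for (int i = 0; i < n_; ++i) idx_[i] = i;
    if (n_ > 0) build(0, n_);
  }

  // k nearest neighbours of a query point; returns pairs (dist2, index)
  void knn(const double* q, int k, std::vector<std::pair<double, int> >& out) const {
    std::priority_queue<std::pair<double, int> > heap;  // max-heap on dist2
    if (n_ > 0) search_knn(0, q, k, heap);
    out.resize(heap.size());
    for (int i = (int)heap.size() - 1; i >= 0; --i) {
      out[i] = heap.top();
      heap.pop();
    }
  }

  int radius_count(const double* q, double r2) const {
    return n_ > 0 ? count_r(0, q, r2) : 0;
  }

private:
  const Rcpp::NumericMatrix& pts_;
  int n_, dim_, leaf_;
  std::vector<int> idx_;
  std::vector<Node> nodes_;

  double coord(int i, int d) const { return pts_(i, d); }

  double dist2(const double* q, int i) const {
    double s = 0.0;
    for (int d = 0; d < dim_; ++d) {
      double t = q[d] - coord(i, d);
      s += t * t;
    }
    return s;
  }

  int build(int start, int end) {
    Node nd;
    nd.start = start;
    nd.end = end;
    nd.axis = -1;
    nd.split = 0.0;
    nd.left = nd.right = -1;
    int id = (int)nodes_.size();
    nodes_.push_back(nd);
    if (end - start <= leaf_) return id;
    // split on the axis of largest spread
    int axis = 0;
    double best_spread = -1.0;
    for (int d = 0; d < dim_; ++d) {
      double lo = coord(idx_[start], d), hi = lo;
      for (int i = start + 1; i < end; ++i) {
        double v = coord(idx_[i], d);
        if (v < lo) lo = v;
        if (v > hi) hi = v;
      }
      if (hi - lo > best_spread) {
        best_spread = hi - lo;
        axis = d;
      }
    }
    if (best_spread <= 0.0) return id;  // all points identical: stay a leaf
    int mid = start + (end - start) / 2;
    std::nth_element(idx_.begin() + start, idx_.begin() + mid, idx_.begin() + end,
                     [&](int a, int b) { return coord(a, axis) < coord(b, axis); });
    // capture the split value before the child builds re-permute idx_
    double split_val = coord(idx_[mid], axis);
    int l = build(start, mid);
    int r = build(mid, end);
    nodes_[id].axis = axis;
    nodes_[id].split = split_val;
    nodes_[id].left = l;
    nodes_[id].right = r;
    return id;
  }

  void scan_leaf(const Node& nd, const double* q, int k,
                 std::priority_queue<std::pair<double, int> >& heap) const {
    for (int i = nd.start; i < nd.end; ++i) {
      double d2 = dist2(q, idx_[i]);
      if ((int)heap.size() < k) {
        heap.push(std::make_pair(d2, idx_[i]));
      } else if (d2 < heap.top().first) {
        heap.pop();
        heap.push(std::make_pair(d2, idx_[i]));
      }
    }
  }

  void search_knn(int id, const double* q, int k,
                  std::priority_queue<std::pair<double, int> >& heap) const {
    const Node& nd = nodes_[id];
    if (nd.axis < 0) {
      scan_leaf(nd, q, k, heap);
      return;
    }
    double delta = q[nd.axis] - nd.split;
    int near = delta < 0 ? nd.left : nd.right;
    int far = delta < 0 ? nd.right : nd.left;
    search_knn(near, q, k, heap);
    if ((int)heap.size() < k || delta * delta < heap.top().first)
      search_knn(far, q, k, heap);
  }

  int count_r(int id, const double* q, double r2) const {
    const Node& nd = nodes_[id];
    if (nd.axis < 0) {
      int c = 0;
      for (int i = nd.start; i < nd.end; ++i)
        if (dist2(q, idx_[i]) <= r2) ++c;
      return c;
    }
    double delta = q[nd.axis] - nd.split;
    int near = delta < 0 ? nd.left : nd.right;
    int far = delta < 0 ? nd.right : nd.left;
    int c = count_r(near, q, r2);
    if (delta * delta <= r2) c += count_r(far, q, r2);
    return c;
  }
};

}  // namespace

// [[Rcpp::export]]
Rcpp::List cpp_knn(Rcpp::NumericMatrix ref, Rcpp::NumericMatrix query, int k) {
  if (ref.ncol() != query.ncol())
    Rcpp::stop("reference and query dimensionality differ");
  if (k < 1) Rcpp::stop("k must be >= 1");
  if (k > ref.nrow()) Rcpp::stop("k exceeds the number of reference points");
  KDTree tree(ref);
  int m = query.nrow(), d = query.ncol();
  Rcpp::IntegerMatrix idx(m, k);
  Rcpp::NumericMatrix dist(m, k);
  std::vector<double> q(d);
  std::vector<std::pair<double, int> > res;
  for (int i = 0; i < m; ++i) {
    for (int j = 0; j < d; ++j) q[j] = query(i, j);
    tree.knn(q.data(), k, res);
    for (int j = 0; j < k; ++j) {
      idx(i, j) = res[j].second + 1;  // 1-based for R
      dist(i, j) = std::sqrt(res[j].first);
    }
  }
  return Rcpp::List::create(Rcpp::Named("idx") = idx, Rcpp::Named("dist") = dist);
}

// [[Rcpp::export]]
Rcpp::IntegerVector cpp_radius_count(Rcpp::NumericMatrix ref,
                                     Rcpp::NumericMatrix query, double radius) {
  if (ref.ncol() != query.ncol())
    Rcpp::stop("reference and query dimensionality differ");
  if (radius <= 0) Rcpp::stop("radius must be positive");
  KDTree tree(ref);
  int m = query.nrow(), d = query.ncol();
  double r2 = radius * radius;
  Rcpp::IntegerVector out(m);
  std::vector<double> q(d);
  for (int i = 0; i < m; ++i) {
    for (int j = 0; j < d; ++j) q[j] = query(i, j);
    out[i] = tree.radius_count(q.data(), r2);
  }
  return out;
}
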