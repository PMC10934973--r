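// Nearest-neighbor kernels shared by rasterization, normal estimation, the
// overlap metric and ICP: a small k-d tree (2D or 3D) plus the line-distance
// scan used by the overlap criterion ||n1 x (p2 - p1)|| < rho.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <limits>
#include <numeric>
#include <vector>

using namespace Rcpp;

namespace {

class KDTree {
public:
  KDTree(const NumericMatrix& P)
      : n_(P.nrow()), d_(P.ncol()), pts_(static_cast<size_t>(n_) * d_),
        idx_(n_) {
    for (int i = 0; i < n_; ++i)
      for (int k = 0; k < d_; ++k) pts_[static_cast<size_t>(i) * d_ + k] = P(i, k);
    std::iota(idx_.begin(), idx_.end(), 0);
    if (n_ > 0) build(0, n_, 0);
  }

  // single nearest neighbor; returns index (0-based) and squared distance
  void nn(const double* q, int& best_i, double& best_d2) const {
    best_i = -1;
    best_d2 = std::numeric_limits<double>::infinity();
    search(q, 0, n_, 0, best_i, best_d2);
  }

  // k nearest neighbors into a max-heap of (d2, index)
  void knn(const double* q, int k,
           std::vector<std::pair<double, int> >& heap) const {
    heap.clear();
    knn_search(q, 0, n_, 0, k, heap);
    std::sort_heap(heap.begin(), heap.end());
  }

private:
  int n_, d_;
  std::vector<double> pts_;
  std::vector<int> idx_;

  double coord(int i, int k) const { return pts_[static_cast<size_t>(i) * d_ + k]; }

  double dist2(const double* q, int i) const {
    double s = 0;
    for (int k = 0; k < d_; ++k) {
      double t = q[k] - coord(i, k);
      s += t * t;
    }
    return s;
  }

  void build(int l, int r, int depth) {
    if (r - l <= 1) return;
    int m = (l + r) / 2;
    int dim = depth % d_;
    const std::vector<double>& pts = pts_;
    int d = d_;
    std::nth_element(idx_.begin() + l, idx_.begin() + m, idx_.begin() + r,
                     [&pts, dim, d](int a, int b) {
                       return pts[static_cast<size_t>(a) * d + dim] <
                              pts[static_cast<size_t>(b) * d + dim];
                     });
    build(l, m, depth + 1);
    build(m + 1, r, depth + 1);
  }

  void search(const double* q, int l, int r, int depth, int& bi,
              double& bd2) const {
    if (l >= r) return;
    int m = (l + r) / 2;
    int dim = depth % d_;
    int i = idx_[m];
    double d2 = dist2(q, i);
    if (d2 < bd2) {
      bd2 = d2;
      bi = i;
    }
    double diff = q[dim] - coord(i, dim);
    if (diff < 0) {
      search(q, l, m, depth + 1, bi, bd2);
      if (diff * diff < bd2) search(q, m + 1, r, depth + 1, bi, bd2);
    } else {
      search(q, m + 1, r, depth + 1, bi, bd2);
      if (diff * diff < bd2) search(q, l, m, depth + 1, bi, bd2);
    }
  }

  void knn_search(const double* q, int l, int r, int depth, int k,
                  std::vector<std::pair<double, int> >& heap) const {
    if (l >= r) return;
    int m = (l + r) / 2;
    int dim = depth % d_;
    int i = idx_[m];
    double d2 = dist2(q, i);
    if ((int)heap.size() < k) {
      heap.push_back(std::make_pair(d2, i));
      std::push_heap(heap.begin(), heap.end());
    } else if (d2 < heap.front().first) {
      std::pop_heap(heap.begin(), heap.end());
      heap.back() = std::make_pair(d2, i);
      std::push_heap(heap.begin(), heap.end());
    }
    double worst = ((int)heap.size() < k)
                       ? std::numeric_limits<double>::infinity()
                       : heap.front().first;
    double diff = q[dim] - coord(i, dim);
    if (diff < 0) {
      knn_search(q, l, m, depth + 1, k, heap);
      worst = ((int)heap.size() < k) ? std::numeric_limits<double>::infinity()
                                     : heap.front().first;
      if (diff * diff < worst) knn_search(q, m + 1, r, depth + 1, k, heap);
    } else {
      knn_search(q, m + 1, r, depth + 1, k, heap);
      worst = ((int)heap.size() < k) ? std::numeric_limits<double>::infinity()
                                     : heap.front().first;
      if (diff * diff < worst) knn_search(q, l, m, depth + 1, k, heap);
    }
  }
};

}  // namespace

// Nearest neighbor in `target` for each row of `query`.
// [[Rcpp::export]]
List cpp_nn(NumericMatrix target, NumericMatrix query) {
  if (target.ncol() != query.ncol())
    stop("target and query must have the same dimension");
  KDTree tree(target);
  int nq = query.nrow(), d = query.ncol();
  IntegerVector index(nq);
  NumericVector dist(nq);
  std::vector<double> q(d);
  for (int i = 0; i < nq; ++i) {
    for (int k = 0; k < d; ++k) q[k] = query(i, k);
    int bi;
    double bd2;
    tree.nn(q.data(), bi, bd2);
    index[i] = bi + 1;
    dist[i] = std::sqrt(bd2);
  }
  return List::create(Named("index") = index, Named("dist") = dist);
}

// k nearest neighbors in `target` for each row of `query` (1-based indices,
// sorted by increasing distance).
// [[Rcpp::export]]
IntegerMatrix cpp_knn(NumericMatrix target, NumericMatrix query, int k) {
  if (target.ncol() != query.ncol())
    stop("target and query must have the same dimension");
  if (k < 1 || k > target.nrow()) stop("k out of range");
  KDTree tree(target);
  int nq = query.nrow(), d = query.ncol();
  IntegerMatrix out(nq, k);
  std::vector<double> q(d);
  std::vector<std::pair<double, int> > heap;
  heap.reserve(k + 1);
  for (int i = 0; i < nq; ++i) {
    for (int kk = 0; kk < d; ++kk) q[kk] = query(i, kk);
    tree.knn(q.data(), k, heap);
    for (int j = 0; j < k; ++j) out(i, j) = heap[j].second + 1;
  }
  return out;
}

// Overlap criterion: point p1[i] overlaps cloud 2 if some p2 satisfies
// ||n1[i] x (p2 - p1[i])|| < rho. Also returns the Euclidean nearest
// neighbor of each p1 in p2. When `full` is true the exact minimum
// line-orthogonal distance is computed for every point (needed for the
// orthogonal distance mode); otherwise the scan exits early once a point
// satisfying the criterion is found.
// [[Rcpp::export]]
List cpp_overlap(NumericMatrix p1, NumericMatrix n1, NumericMatrix p2,
                 double rho, bool full) {
  int n = p1.nrow(), m = p2.nrow();
  if (n1.nrow() != n) stop("normals must match points");
  if (p1.ncol() != 3 || p2.ncol() != 3 || n1.ncol() != 3)
    stop("points must be N x 3");
  KDTree tree(p2);
  LogicalVector mask(n);
  IntegerVector nn_index(n);
  NumericVector nn_dist(n);
  NumericVector min_orth(n, NA_REAL);
  double q[3];
  for (int i = 0; i < n; ++i) {
    double px = p1(i, 0), py = p1(i, 1), pz = p1(i, 2);
    double nx = n1(i, 0), ny = n1(i, 1), nz = n1(i, 2);
    q[0] = px; q[1] = py; q[2] = pz;
    int bi;
    double bd2;
    tree.nn(q, bi, bd2);
    nn_index[i] = bi + 1;
    nn_dist[i] = std::sqrt(bd2);
    // fast path: test the Euclidean nearest neighbor first
    bool hit = false;
    {
      double dx = p2(bi, 0) - px, dy = p2(bi, 1) - py, dz = p2(bi, 2) - pz;
      double cx = ny * dz - nz * dy, cy = nz * dx - nx * dz,
             cz = nx * dy - ny * dx;
      double c = std::sqrt(cx * cx + cy * cy + cz * cz);
      if (c < rho) hit = true;
      if (full) min_orth[i] = c;
    }
    if (!hit || full) {
      double best = full ? min_orth[i] : std::numeric_limits<double>::infinity();
      for (int j = 0; j < m; ++j) {
        double dx = p2(j, 0) - px, dy = p2(j, 1) - py, dz = p2(j, 2) - pz;
        double cx = ny * dz - nz * dy, cy = nz * dx - nx * dz,
               cz = nx * dy - ny * dx;
        double c2 = cx * cx + cy * cy + cz * cz;
        if (c2 < best * best) {
          best = std::sqrt(c2);
          if (best < rho) {
            hit = true;
            if (!full) break;
          }
        }
      }
      if (full) min_orth[i] = best;
    }
    mask[i] = hit;
  }
  List out = List::create(Named("mask") = mask, Named("nn_index") = nn_index,
                          Named("nn_dist") = nn_dist);
  if (full) out["min_orth"] = min_orth;
  return out;
}

// Per-point surface normals from the k-nearest-neighbor covariance: smallest
// eigenvector of the 3x3 neighborhood covariance (cyclic Jacobi). Returns
// unoriented normals plus a degeneracy flag (neighborhood with rank < 2).
// [[Rcpp::export]]
List cpp_normals(NumericMatrix pts, int k) {
  int n = pts.nrow();
  if (pts.ncol() != 3) stop("points must be N x 3");
  if (k < 3 || k > n) stop("k must be in [3, n]");
  KDTree tree(pts);
  NumericMatrix normals(n, 3);
  LogicalVector degenerate(n);
  std::vector<std::pair<double, int> > heap;
  heap.reserve(k + 1);
  double q[3];
  for (int i = 0; i < n; ++i) {
    q[0] = pts(i, 0); q[1] = pts(i, 1); q[2] = pts(i, 2);
    tree.knn(q, k, heap);
    double mx = 0, my = 0, mz = 0;
    for (int j = 0; j < k; ++j) {
      int id = heap[j].second;
      mx += pts(id, 0); my += pts(id, 1); mz += pts(id, 2);
    }
    mx /= k; my /= k; mz /= k;
    double C[3][3] = {{0, 0, 0}, {0, 0, 0}, {0, 0, 0}};
    for (int j = 0; j < k; ++j) {
      int id = heap[j].second;
      double dx = pts(id, 0) - mx, dy = pts(id, 1) - my, dz = pts(id, 2) - mz;
      C[0][0] += dx * dx; C[0][1] += dx * dy; C[0][2] += dx * dz;
      C[1][1] += dy * dy; C[1][2] += dy * dz; C[2][2] += dz * dz;
    }
    C[1][0] = C[0][1]; C[2][0] = C[0][2]; C[2][1] = C[1][2];
    // cyclic Jacobi eigen-decomposition of the symmetric 3x3 matrix
    double V[3][3] = {{1, 0, 0}, {0, 1, 0}, {0, 0, 1}};
    for (int sweep = 0; sweep < 20; ++sweep) {
      double off = C[0][1] * C[0][1] + C[0][2] * C[0][2] + C[1][2] * C[1][2];
      if (off < 1e-30) break;
      for (int p = 0; p < 2; ++p) {
        for (int qq = p + 1; qq < 3; ++qq) {
          if (std::fabs(C[p][qq]) < 1e-300) continue;
          double theta = (C[qq][qq] - C[p][p]) / (2.0 * C[p][qq]);
          double t = (theta >= 0 ? 1.0 : -1.0) /
                     (std::fabs(theta) + std::sqrt(theta * theta + 1.0));
          double c = 1.0 / std::sqrt(t * t + 1.0);
          double s = t * c;
          for (int r = 0; r < 3; ++r) {
            double crp = C[r][p], crq = C[r][qq];
            C[r][p] = c * crp - s * crq;
            C[r][qq] = s * crp + c * crq;
          }
          for (int r = 0; r < 3; ++r) {
            double cpr = C[p][r], cqr = C[qq][r];
            C[p][r] = c * cpr - s * cqr;
            C[qq][r] = s * cpr + c * cqr;
          }
          for (int r = 0; r < 3; ++r) {
            double vrp = V[r][p], vrq = V[r][qq];
            V[r][p] = c * vrp - s * vrq;
            V[r][qq] = s * vrp + c * vrq;
          }
        }
      }
    }
    double ev[3] = {C[0][0], C[1][1], C[2][2]};
    int i_min = 0, i_max = 0;
    for (int r = 1; r < 3; ++r) {
      if (ev[r] < ev[i_min]) i_min = r;
      if (ev[r] > ev[i_max]) i_max = r;
    }
    int i_mid = 3 - i_min - i_max;
    if (i_min == i_max) i_mid = i_min;  // all equal
    double nrm = std::sqrt(V[0][i_min] * V[0][i_min] +
                           V[1][i_min] * V[1][i_min] +
                           V[2][i_min] * V[2][i_min]);
    normals(i, 0) = V[0][i_min] / nrm;
    normals(i, 1) = V[1][i_min] / nrm;
    normals(i, 2) = V[2][i_min] / nrm;
    degenerate[i] = (ev[i_mid] <= 1e-10 * std::max(ev[i_max], 1e-300));
  }
  return List::create(Named("normals") = normals,
                      Named("degenerate") = degenerate);
}
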