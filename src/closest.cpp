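#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Nearest-vertex queries use a median-split k-d tree over the mesh vertices;
// the tree is stored implicitly as a reordered index array (each range's
// median is the node, halves are the subtrees).

struct KDTree {
  std::vector<double> pts;  // 3*n, xyz interleaved
  std::vector<int> idx;     // permutation of 0..n-1 in tree order
  int n;

  double coord(int i, int ax) const { return pts[3 * i + ax]; }

  void build(int lo, int hi, int depth) {
    if (hi - lo <= 1) return;
    int mid = lo + (hi - lo) / 2;
    int ax = depth % 3;
    std::nth_element(idx.begin() + lo, idx.begin() + mid, idx.begin() + hi,
                     [&](int a, int b) { return coord(a, ax) < coord(b, ax); });
    build(lo, mid, depth + 1);
    build(mid + 1, hi, depth + 1);
  }

  void query(const double* q, int lo, int hi, int depth,
             double& best_d2, int& best_i) const {
    if (hi <= lo) return;
    int mid = lo + (hi - lo) / 2;
    int i = idx[mid];
    double dx = q[0] - coord(i, 0), dy = q[1] - coord(i, 1), dz = q[2] - coord(i, 2);
    double d2 = dx * dx + dy * dy + dz * dz;
    if (d2 < best_d2 || (d2 == best_d2 && i < best_i)) { best_d2 = d2; best_i = i; }
    int ax = depth % 3;
    double diff = q[ax] - coord(i, ax);
    int near_lo = lo, near_hi = mid, far_lo = mid + 1, far_hi = hi;
    if (diff > 0) { std::swap(near_lo, far_lo); std::swap(near_hi, far_hi); }
    query(q, near_lo, near_hi, depth + 1, best_d2, best_i);
    if (diff * diff <= best_d2)
      query(q, far_lo, far_hi, depth + 1, best_d2, best_i);
  }
};

// [[Rcpp::export]]
SEXP cpp_kd_build(NumericMatrix pts) {
  if (pts.ncol() != 3) stop("points must be an n x 3 matrix");
  KDTree* t = new KDTree();
  t->n = pts.nrow();
  t->pts.resize(3 * t->n);
  t->idx.resize(t->n);
  for (int i = 0; i < t->n; ++i) {
    t->pts[3 * i] = pts(i, 0);
    t->pts[3 * i + 1] = pts(i, 1);
    t->pts[3 * i + 2] = pts(i, 2);
    t->idx[i] = i;
  }
  t->build(0, t->n, 0);
  XPtr<KDTree> p(t, true);
  return p;
}

// [[Rcpp::export]]
List cpp_kd_query(SEXP tree, NumericMatrix queries) {
  XPtr<KDTree> t(tree);
  int m = queries.nrow();
  IntegerVector index(m);
  NumericVector dist(m);
  double q[3];
  for (int j = 0; j < m; ++j) {
    q[0] = queries(j, 0); q[1] = queries(j, 1); q[2] = queries(j, 2);
    double best_d2 = R_PosInf;
    int best_i = t->n;
    t->query(q, 0, t->n, 0, best_d2, best_i);
    index[j] = best_i + 1;
    dist[j] = std::sqrt(best_d2);
  }
  return List::create(_["index"] = index, _["distance"] = dist);
}

// Closest point on a single triangle (Ericson, Real-Time Collision Detection)
static void closest_on_triangle(const double* p, const double* a,
                                const double* b, const double* c,
                                double* out) {
  double ab[3], ac[3], ap[3];
  for (int k = 0; k < 3; ++k) {
    ab[k] = b[k] - a[k]; ac[k] = c[k] - a[k]; ap[k] = p[k] - a[k];
  }
  double d1 = ab[0]*ap[0] + ab[1]*ap[1] + ab[2]*ap[2];
  double d2 = ac[0]*ap[0] + ac[1]*ap[1] + ac[2]*ap[2];
  if (d1 <= 0 && d2 <= 0) { for (int k = 0; k < 3; ++k) out[k] = a[k]; return; }

  double bp[3];
  for (int k = 0; k < 3; ++k) bp[k] = p[k] - b[k];
  double d3 = ab[0]*bp[0] + ab[1]*bp[1] + ab[2]*bp[2];
  double d4 = ac[0]*bp[0] + ac[1]*bp[1] + ac[2]*bp[2];
  if (d3 >= 0 && d4 <= d3) { for (int k = 0; k < 3; ++k) out[k] = b[k]; return; }

  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double v = d1 / (d1 - d3);
    for (int k = 0; k < 3; ++k) out[k] = a[k] + v * ab[k];
    return;
  }

  double cp[3];
  for (int k = 0; k < 3; ++k) cp[k] = p[k] - c[k];
  double d5 = ab[0]*cp[0] + ab[1]*cp[1] + ab[2]*cp[2];
  double d6 = ac[0]*cp[0] + ac[1]*cp[1] + ac[2]*cp[2];
  if (d6 >= 0 && d5 <= d6) { for (int k = 0; k < 3; ++k) out[k] = c[k]; return; }

  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double w = d2 / (d2 - d6);
    for (int k = 0; k < 3; ++k) out[k] = a[k] + w * ac[k];
    return;
  }

  double va = d3 * d6 - d5 * d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int k = 0; k < 3; ++k) out[k] = b[k] + w * (c[k] - b[k]);
    return;
  }

  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int k = 0; k < 3; ++k) out[k] = a[k] + v * ab[k] + w * ac[k];
}

// Exact closest point on the triangulated surface. The nearest mesh vertex
// (k-d tree) seeds the search radius; per-triangle AABB distance prunes the
// remaining triangles.
// [[Rcpp::export]]
List cpp_closest_triangle(NumericMatrix V, IntegerMatrix F, NumericMatrix Q,
                          SEXP tree) {
  int nf = F.nrow(), m = Q.nrow();
  if (F.ncol() != 3) stop("faces must be an m x 3 matrix");
  XPtr<KDTree> t(tree);

  // per-triangle AABBs
  std::vector<double> lo(3 * nf), hi(3 * nf);
  for (int f = 0; f < nf; ++f) {
    for (int k = 0; k < 3; ++k) {
      double va = V(F(f, 0), k), vb = V(F(f, 1), k), vc = V(F(f, 2), k);
      lo[3 * f + k] = std::min(va, std::min(vb, vc));
      hi[3 * f + k] = std::max(va, std::max(vb, vc));
    }
  }

  NumericMatrix point(m, 3);
  NumericVector dist(m);
  IntegerVector face(m);
  double q[3], a[3], b[3], c[3], cp[3];

  for (int j = 0; j < m; ++j) {
    q[0] = Q(j, 0); q[1] = Q(j, 1); q[2] = Q(j, 2);
    double best_d2 = R_PosInf;
    int seed = t->n;
    t->query(q, 0, t->n, 0, best_d2, seed);  // upper bound: nearest vertex
    int best_f = -1;
    double best_p[3] = {V(seed, 0), V(seed, 1), V(seed, 2)};

    for (int f = 0; f < nf; ++f) {
      double box_d2 = 0;
      for (int k = 0; k < 3; ++k) {
        double d = 0;
        if (q[k] < lo[3 * f + k]) d = lo[3 * f + k] - q[k];
        else if (q[k] > hi[3 * f + k]) d = q[k] - hi[3 * f + k];
        box_d2 += d * d;
      }
      if (box_d2 > best_d2) continue;
      for (int k = 0; k < 3; ++k) {
        a[k] = V(F(f, 0), k); b[k] = V(F(f, 1), k); c[k] = V(F(f, 2), k);
      }
      closest_on_triangle(q, a, b, c, cp);
      double d2 = 0;
      for (int k = 0; k < 3; ++k) {
        double d = q[k] - cp[k];
        d2 += d * d;
      }
      if (d2 < best_d2) {
        best_d2 = d2;
        best_f = f;
        for (int k = 0; k < 3; ++k) best_p[k] = cp[k];
      }
    }
    for (int k = 0; k < 3; ++k) point(j, k) = best_p[k];
    dist[j] = std::sqrt(best_d2);
    face[j] = best_f + 1;  // 0 if the seed vertex was never beaten (degenerate)
  }
  return List::create(_["point"] = point, _["distance"] = dist,
                      _["face"] = face);
}
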