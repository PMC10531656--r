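// Convex-hull volumes and hull-intersection volumes in low dimension
// (d = 2..6) by exhaustive facet enumeration.  Point counts here are
// small (a species pool of a few dozen), so O(C(n,d) * n) enumeration
// is faster in practice than maintaining an incremental hull, and it is
// robust to coplanar point sets because facets are deduplicated as
// hyperplanes rather than simplices.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

typedef std::vector<double> Vec;
typedef std::vector<Vec> Mat;

static const int MAXD = 6;

// determinant of a small dense matrix (destroys its argument)
static double det_small(Mat a) {
  int n = (int)a.size();
  if (n == 0) return 1.0;
  double det = 1.0;
  for (int i = 0; i < n; ++i) {
    int piv = i;
    for (int r = i + 1; r < n; ++r)
      if (std::fabs(a[r][i]) > std::fabs(a[piv][i])) piv = r;
    if (std::fabs(a[piv][i]) < 1e-300) return 0.0;
    if (piv != i) { std::swap(a[piv], a[i]); det = -det; }
    det *= a[i][i];
    for (int r = i + 1; r < n; ++r) {
      double f = a[r][i] / a[i][i];
      for (int c = i; c < n; ++c) a[r][c] -= f * a[i][c];
    }
  }
  return det;
}

// generalized cross product: normal to (d-1) vectors in R^d
static Vec cross_gen(const Mat& v, int d) {
  Vec n(d);
  Mat m(d - 1, Vec(d - 1));
  for (int j = 0; j < d; ++j) {
    for (int r = 0; r < d - 1; ++r) {
      int cc = 0;
      for (int c = 0; c < d; ++c)
        if (c != j) m[r][cc++] = v[r][c];
    }
    n[j] = ((j % 2) ? -1.0 : 1.0) * det_small(m);
  }
  return n;
}

static double dot(const Vec& a, const Vec& b) {
  double s = 0.0;
  for (size_t i = 0; i < a.size(); ++i) s += a[i] * b[i];
  return s;
}

struct Facet {
  Vec n;      // unit outward normal
  double b;   // offset: n . x <= b for hull points
};

// characteristic coordinate scale of a point set
static double coord_scale(const Mat& pts) {
  double s = 0.0;
  for (size_t i = 0; i < pts.size(); ++i)
    for (size_t j = 0; j < pts[i].size(); ++j)
      s = std::max(s, std::fabs(pts[i][j]));
  return std::max(s, 1e-12);
}

static Mat dedup_points(const Mat& pts, double tol) {
  Mat out;
  for (size_t i = 0; i < pts.size(); ++i) {
    bool dup = false;
    for (size_t k = 0; k < out.size() && !dup; ++k) {
      double dmax = 0.0;
      for (size_t j = 0; j < pts[i].size(); ++j)
        dmax = std::max(dmax, std::fabs(pts[i][j] - out[k][j]));
      dup = dmax <= tol;
    }
    if (!dup) out.push_back(pts[i]);
  }
  return out;
}

// affine rank of a point set via Gram-Schmidt on centred points
static int affine_rank(const Mat& pts, int d, double tol) {
  int n = (int)pts.size();
  if (n <= 1) return 0;
  Mat basis;
  for (int i = 1; i < n; ++i) {
    Vec v(d);
    for (int j = 0; j < d; ++j) v[j] = pts[i][j] - pts[0][j];
    for (size_t k = 0; k < basis.size(); ++k) {
      double p = dot(v, basis[k]);
      for (int j = 0; j < d; ++j) v[j] -= p * basis[k][j];
    }
    double nv = std::sqrt(dot(v, v));
    if (nv > tol) {
      for (int j = 0; j < d; ++j) v[j] /= nv;
      basis.push_back(v);
      if ((int)basis.size() == d) return d;
    }
  }
  return (int)basis.size();
}

// enumerate facets of the hull of pts (assumed full-dimensional in d)
static std::vector<Facet> enum_facets(const Mat& pts, int d, double scale) {
  int n = (int)pts.size();
  std::vector<Facet> facets;
  double tol_side = 1e-8 * scale;
  Vec c(d, 0.0);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < d; ++j) c[j] += pts[i][j] / n;

  std::vector<int> idx(d);
  for (int i = 0; i < d; ++i) idx[i] = i;
  Mat span(d - 1, Vec(d));
  Vec nor(d);
  while (true) {
    // hyperplane through pts[idx[0..d-1]]
    for (int r = 0; r < d - 1; ++r)
      for (int j = 0; j < d; ++j)
        span[r][j] = pts[idx[r + 1]][j] - pts[idx[0]][j];
    if (d == 2) {
      nor[0] = -span[0][1];
      nor[1] = span[0][0];
    } else if (d == 3) {
      nor[0] = span[0][1] * span[1][2] - span[0][2] * span[1][1];
      nor[1] = span[0][2] * span[1][0] - span[0][0] * span[1][2];
      nor[2] = span[0][0] * span[1][1] - span[0][1] * span[1][0];
    } else {
      nor = cross_gen(span, d);
    }
    double nn = std::sqrt(dot(nor, nor));
    if (nn > 1e-12 * std::pow(scale, d - 1)) {
      for (int j = 0; j < d; ++j) nor[j] /= nn;
      double b = dot(nor, pts[idx[0]]);
      // orient outward (centroid on the <= side)
      if (dot(nor, c) > b) {
        for (int j = 0; j < d; ++j) nor[j] = -nor[j];
        b = -b;
      }
      bool all_in = true;
      for (int i = 0; i < n && all_in; ++i)
        all_in = dot(nor, pts[i]) <= b + tol_side;
      if (all_in) {
        bool seen = false;
        for (size_t k = 0; k < facets.size() && !seen; ++k) {
          double dn = 0.0;
          for (int j = 0; j < d; ++j)
            dn = std::max(dn, std::fabs(facets[k].n[j] - nor[j]));
          seen = dn < 1e-6 && std::fabs(facets[k].b - b) < 1e-6 * scale;
        }
        if (!seen) facets.push_back(Facet{nor, b});
      }
    }
    // next combination
    int i = d - 1;
    while (i >= 0 && idx[i] == n - d + i) --i;
    if (i < 0) break;
    ++idx[i];
    for (int k = i + 1; k < d; ++k) idx[k] = idx[k - 1] + 1;
  }
  return facets;
}

// volume of the convex hull; *degenerate set true when affine rank < d
static double hull_volume_impl(const Mat& pts_in, int d, bool* degenerate) {
  *degenerate = false;
  double scale = coord_scale(pts_in);
  Mat pts = dedup_points(pts_in, 1e-10 * scale);
  int n = (int)pts.size();
  if (d == 1) {
    if (n < 2) { *degenerate = true; return 0.0; }
    double lo = pts[0][0], hi = pts[0][0];
    for (int i = 1; i < n; ++i) {
      lo = std::min(lo, pts[i][0]);
      hi = std::max(hi, pts[i][0]);
    }
    return hi - lo;
  }
  if (n < d + 1 || affine_rank(pts, d, 1e-9 * scale) < d) {
    *degenerate = true;
    return 0.0;
  }
  Vec c(d, 0.0);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < d; ++j) c[j] += pts[i][j] / n;
  std::vector<Facet> facets = enum_facets(pts, d, scale);
  double vol = 0.0;
  for (size_t f = 0; f < facets.size(); ++f) {
    const Facet& fc = facets[f];
    // points lying on this facet, projected to an orthonormal basis of it
    Mat on;
    for (int i = 0; i < n; ++i)
      if (std::fabs(dot(fc.n, pts[i]) - fc.b) <= 1e-7 * scale)
        on.push_back(pts[i]);
    if ((int)on.size() < d) continue;
    // orthonormal basis of the hyperplane
    Mat basis;
    for (int e = 0; e < d && (int)basis.size() < d - 1; ++e) {
      Vec v(d, 0.0);
      v[e] = 1.0;
      double p = dot(v, fc.n);
      for (int j = 0; j < d; ++j) v[j] -= p * fc.n[j];
      for (size_t k = 0; k < basis.size(); ++k) {
        double q = dot(v, basis[k]);
        for (int j = 0; j < d; ++j) v[j] -= q * basis[k][j];
      }
      double nv = std::sqrt(dot(v, v));
      if (nv > 1e-9) {
        for (int j = 0; j < d; ++j) v[j] /= nv;
        basis.push_back(v);
      }
    }
    if ((int)basis.size() != d - 1) continue;
    Mat proj(on.size(), Vec(d - 1));
    for (size_t i = 0; i < on.size(); ++i) {
      Vec rel(d);
      for (int j = 0; j < d; ++j) rel[j] = on[i][j] - on[0][j];
      for (int k = 0; k < d - 1; ++k) proj[i][k] = dot(rel, basis[k]);
    }
    bool sub_deg = false;
    double area = hull_volume_impl(proj, d - 1, &sub_deg);
    if (sub_deg) continue;
    double h = fc.b - dot(fc.n, c);  // >= 0 by orientation
    vol += area * h / d;
  }
  return vol;
}

static Mat as_mat(const NumericMatrix& x) {
  Mat p(x.nrow(), Vec(x.ncol()));
  for (int i = 0; i < x.nrow(); ++i)
    for (int j = 0; j < x.ncol(); ++j) p[i][j] = x(i, j);
  return p;
}

// [[Rcpp::export]]
double cpp_hull_volume(NumericMatrix x) {
  int d = x.ncol();
  if (d < 1 || d > MAXD) stop("hull dimension must be in 1..%d", MAXD);
  bool deg = false;
  double v = hull_volume_impl(as_mat(x), d, &deg);
  if (deg) return NA_REAL;
  return v;
}

// [[Rcpp::export]]
List cpp_hull_facets(NumericMatrix x) {
  int d = x.ncol();
  if (d < 2 || d > MAXD) stop("hull dimension must be in 2..%d", MAXD);
  Mat pts = dedup_points(as_mat(x), 1e-10 * coord_scale(as_mat(x)));
  double scale = coord_scale(pts);
  if ((int)pts.size() < d + 1 || affine_rank(pts, d, 1e-9 * scale) < d)
    stop("point set is degenerate (affine rank < %d)", d);
  std::vector<Facet> fa = enum_facets(pts, d, scale);
  NumericMatrix normals(fa.size(), d);
  NumericVector offs(fa.size());
  for (size_t i = 0; i < fa.size(); ++i) {
    for (int j = 0; j < d; ++j) normals(i, j) = fa[i].n[j];
    offs[i] = fa[i].b;
  }
  return List::create(_["normals"] = normals, _["offsets"] = offs);
}

// solve d x d linear system; returns false when singular
static bool solve_small(Mat a, Vec b, Vec& x, double tol) {
  int n = (int)a.size();
  for (int i = 0; i < n; ++i) {
    int piv = i;
    for (int r = i + 1; r < n; ++r)
      if (std::fabs(a[r][i]) > std::fabs(a[piv][i])) piv = r;
    if (std::fabs(a[piv][i]) < tol) return false;
    if (piv != i) { std::swap(a[piv], a[i]); std::swap(b[piv], b[i]); }
    for (int r = i + 1; r < n; ++r) {
      double f = a[r][i] / a[i][i];
      for (int c = i; c < n; ++c) a[r][c] -= f * a[i][c];
      b[r] -= f * b[i];
    }
  }
  x.assign(n, 0.0);
  for (int i = n - 1; i >= 0; --i) {
    double s = b[i];
    for (int c = i + 1; c < n; ++c) s -= a[i][c] * x[c];
    x[i] = s / a[i][i];
  }
  return true;
}

// volume of the intersection of the hulls of two point sets: collect the
// facet half-spaces of both hulls, enumerate candidate vertices as
// intersections of d facet hyperplanes, keep the feasible ones, and take
// the hull volume of the resulting vertex set.
// [[Rcpp::export]]
double cpp_hull_intersection_volume(NumericMatrix a, NumericMatrix b) {
  int d = a.ncol();
  if (b.ncol() != d) stop("point sets must share dimensionality");
  if (d < 2 || d > MAXD) stop("hull dimension must be in 2..%d", MAXD);
  Mat pa = as_mat(a), pb = as_mat(b);
  double scale = std::max(coord_scale(pa), coord_scale(pb));
  double rtol = 1e-9 * scale;
  if (affine_rank(dedup_points(pa, rtol), d, rtol) < d ||
      affine_rank(dedup_points(pb, rtol), d, rtol) < d)
    stop("point set is degenerate (affine rank < %d)", d);
  std::vector<Facet> fa = enum_facets(pa, d, scale);
  std::vector<Facet> fb = enum_facets(pb, d, scale);
  std::vector<Facet> all(fa);
  all.insert(all.end(), fb.begin(), fb.end());
  int m = (int)all.size();
  double feas_tol = 1e-7 * scale;

  Mat verts;
  std::vector<int> idx(d);
  for (int i = 0; i < d; ++i) idx[i] = i;
  while (true) {
    Mat A(d, Vec(d));
    Vec rhs(d);
    for (int r = 0; r < d; ++r) {
      for (int j = 0; j < d; ++j) A[r][j] = all[idx[r]].n[j];
      rhs[r] = all[idx[r]].b;
    }
    Vec x;
    if (solve_small(A, rhs, x, 1e-9)) {
      bool ok = true;
      for (int k = 0; k < m && ok; ++k)
        ok = dot(all[k].n, x) <= all[k].b + feas_tol;
      if (ok) verts.push_back(x);
    }
    int i = d - 1;
    while (i >= 0 && idx[i] == m - d + i) --i;
    if (i < 0) break;
    ++idx[i];
    for (int k = i + 1; k < d; ++k) idx[k] = idx[k - 1] + 1;
  }
  if ((int)verts.size() < d + 1) return 0.0;
  bool deg = false;
  double v = hull_volume_impl(verts, d, &deg);
  return deg ? 0.0 : v;
}

// per-site convex-hull volumes over the species coordinates present in
// each row of a binary community matrix; NA for degenerate/too-small sets
// [[Rcpp::export]]
NumericVector cpp_site_hull_volumes(NumericMatrix coords, IntegerMatrix comm) {
  int d = coords.ncol();
  if (d < 1 || d > MAXD) stop("hull dimension must be in 1..%d", MAXD);
  if (comm.ncol() != coords.nrow())
    stop("community columns must match coordinate rows");
  int ns = comm.nrow(), sp = comm.ncol();
  NumericVector out(ns);
  for (int i = 0; i < ns; ++i) {
    Mat pts;
    for (int j = 0; j < sp; ++j)
      if (comm(i, j) == 1) {
        Vec p(d);
        for (int k = 0; k < d; ++k) p[k] = coords(j, k);
        pts.push_back(p);
      }
    if ((int)pts.size() < d + 1) {
      out[i] = NA_REAL;
      continue;
    }
    bool deg = false;
    double v = hull_volume_impl(pts, d, &deg);
    out[i] = deg ? NA_REAL : v;
  }
  return out;
}

// [[Rcpp::export]]
LogicalVector cpp_in_hull(NumericMatrix hull_pts, NumericMatrix query) {
  int d = hull_pts.ncol();
  if (query.ncol() != d) stop("dimension mismatch");
  Mat pts = as_mat(hull_pts);
  double scale = coord_scale(pts);
  std::vector<Facet> fa = enum_facets(pts, d, scale);
  double tol = 1e-7 * scale;
  int nq = query.nrow();
  LogicalVector out(nq);
  Vec q(d);
  for (int i = 0; i < nq; ++i) {
    for (int j = 0; j < d; ++j) q[j] = query(i, j);
    bool in = true;
    for (size_t k = 0; k < fa.size() && in; ++k)
      in = dot(fa[k].n, q) <= fa[k].b + tol;
    out[i] = in;
  }
  return out;
}
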