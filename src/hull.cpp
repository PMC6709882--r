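#include <Rcpp.h>
#include <vector>
#include <map>
#include <cmath>
using namespace Rcpp;

// Incremental 3D convex hull, volume only. Points are nm-scale; tolerances
// are relative to the cloud extent so blobs of any magnitude behave alike.

namespace {

struct Face {
  int a, b, c;
  bool alive;
};

inline void sub3(const double* p, const double* q, double* out) {
  out[0] = p[0] - q[0]; out[1] = p[1] - q[1]; out[2] = p[2] - q[2];
}

inline void cross3(const double* u, const double* v, double* out) {
  out[0] = u[1] * v[2] - u[2] * v[1];
  out[1] = u[2] * v[0] - u[0] * v[2];
  out[2] = u[0] * v[1] - u[1] * v[0];
}

inline double dot3(const double* u, const double* v) {
  return u[0] * v[0] + u[1] * v[1] + u[2] * v[2];
}

inline double norm3(const double* u) { return std::sqrt(dot3(u, u)); }

// signed distance of point p from plane of face (a,b,c), positive outside
double plane_dist(const std::vector<double>& P, int a, int b, int c,
                  const double* p) {
  double e1[3], e2[3], n[3], d[3];
  sub3(&P[3 * b], &P[3 * a], e1);
  sub3(&P[3 * c], &P[3 * a], e2);
  cross3(e1, e2, n);
  double nn = norm3(n);
  if (nn == 0.0) return 0.0;
  sub3(p, &P[3 * a], d);
  return dot3(n, d) / nn;
}

} // namespace

//' @noRd
// [[Rcpp::export(name = "cpp_hull_volume")]]
double cpp_hull_volume(NumericMatrix pts) {
  const int n = pts.nrow();
  if (n < 4) return 0.0;

  std::vector<double> P(3 * n);
  double lo[3] = {R_PosInf, R_PosInf, R_PosInf};
  double hi[3] = {R_NegInf, R_NegInf, R_NegInf};
  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < 3; ++k) {
      double v = pts(i, k);
      P[3 * i + k] = v;
      if (v < lo[k]) lo[k] = v;
      if (v > hi[k]) hi[k] = v;
    }
  }
  double scale = 0.0;
  for (int k = 0; k < 3; ++k) scale = std::max(scale, hi[k] - lo[k]);
  if (scale == 0.0) return 0.0;
  const double tol = 1e-10 * scale;

  // initial simplex: farthest pair along extent, then farthest from line,
  // then farthest from plane
  int i0 = 0, i1 = -1;
  double best = -1.0;
  for (int i = 1; i < n; ++i) {
    double d[3];
    sub3(&P[3 * i], &P[3 * i0], d);
    double dd = norm3(d);
    if (dd > best) { best = dd; i1 = i; }
  }
  if (best <= tol) return 0.0;

  int i2 = -1; best = -1.0;
  double e1[3];
  sub3(&P[3 * i1], &P[3 * i0], e1);
  for (int i = 0; i < n; ++i) {
    double d[3], cr[3];
    sub3(&P[3 * i], &P[3 * i0], d);
    cross3(e1, d, cr);
    double dd = norm3(cr) / norm3(e1);
    if (dd > best) { best = dd; i2 = i; }
  }
  if (best <= tol) return 0.0; // collinear

  int i3 = -1; best = -1.0;
  for (int i = 0; i < n; ++i) {
    double dd = std::fabs(plane_dist(P, i0, i1, i2, &P[3 * i]));
    if (dd > best) { best = dd; i3 = i; }
  }
  if (best <= tol) return 0.0; // coplanar

  // interior reference point
  double ctr[3];
  for (int k = 0; k < 3; ++k)
    ctr[k] = (P[3 * i0 + k] + P[3 * i1 + k] + P[3 * i2 + k] + P[3 * i3 + k]) / 4.0;

  std::vector<Face> faces;
  auto add_face = [&](int a, int b, int c) {
    // orient so the interior point is behind the face
    if (plane_dist(P, a, b, c, ctr) > 0) std::swap(b, c);
    faces.push_back({a, b, c, true});
  };
  add_face(i0, i1, i2);
  add_face(i0, i1, i3);
  add_face(i0, i2, i3);
  add_face(i1, i2, i3);

  for (int i = 0; i < n; ++i) {
    if (i == i0 || i == i1 || i == i2 || i == i3) continue;
    const double* p = &P[3 * i];
    std::vector<int> visible;
    for (size_t f = 0; f < faces.size(); ++f) {
      if (!faces[f].alive) continue;
      if (plane_dist(P, faces[f].a, faces[f].b, faces[f].c, p) > tol)
        visible.push_back((int)f);
    }
    if (visible.empty()) continue;

    // horizon = directed edges of visible faces whose reverse edge is not
    // in a visible face
    std::map<std::pair<int, int>, int> edge_count;
    for (int f : visible) {
      const Face& F = faces[f];
      int e[3][2] = {{F.a, F.b}, {F.b, F.c}, {F.c, F.a}};
      for (auto& ed : e) edge_count[{ed[0], ed[1]}]++;
    }
    std::vector<std::pair<int, int>> horizon;
    for (auto& kv : edge_count) {
      auto rev = std::make_pair(kv.first.second, kv.first.first);
      if (edge_count.find(rev) == edge_count.end())
        horizon.push_back(kv.first);
    }
    for (int f : visible) faces[f].alive = false;
    for (auto& ed : horizon) add_face(ed.first, ed.second, i);
  }

  double vol6 = 0.0;
  for (const Face& F : faces) {
    if (!F.alive) continue;
    double u[3], v[3], w[3], cr[3];
    sub3(&P[3 * F.a], ctr, u);
    sub3(&P[3 * F.b], ctr, v);
    sub3(&P[3 * F.c], ctr, w);
    cross3(v, w, cr);
    vol6 += dot3(u, cr);
  }
  return vol6 / 6.0;
}
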