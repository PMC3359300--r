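// 3-D convex hull (quickhull) returning facet planes, used for the
// distance-to-territory-surface observable. For a point inside a convex
// polytope the distance to the boundary equals the minimum over facets of
// the distance to the facet plane (the inscribed ball of that radius lies in
// every defining half-space), so facet planes are all that is needed.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <map>
#include <utility>
#include <algorithm>

using namespace Rcpp;

namespace {

struct Vec3 {
  double x, y, z;
  Vec3 operator-(const Vec3& o) const { return { x - o.x, y - o.y, z - o.z }; }
  Vec3 operator+(const Vec3& o) const { return { x + o.x, y + o.y, z + o.z }; }
  Vec3 operator*(double s) const { return { x * s, y * s, z * s }; }
};
static double dot(const Vec3& a, const Vec3& b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
static Vec3 cross(const Vec3& a, const Vec3& b) {
  return { a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x };
}
static double norm(const Vec3& a) { return std::sqrt(dot(a, a)); }

struct Face {
  int a, b, c;
  Vec3 n;          // unit outward normal
  double off;      // n . x = off on the facet plane
  std::vector<int> outside;
  bool alive = true;
};

bool make_face(Face& f, const std::vector<Vec3>& P, int a, int b, int c,
               const Vec3& interior, double eps) {
  Vec3 nv = cross(P[b] - P[a], P[c] - P[a]);
  double ln = norm(nv);
  if (ln < eps) return false;                 // degenerate sliver
  nv = nv * (1.0 / ln);
  double off = dot(nv, P[a]);
  if (dot(nv, interior) > off) { nv = nv * (-1.0); off = -off; std::swap(b, c); }
  f.a = a; f.b = b; f.c = c; f.n = nv; f.off = off;
  f.alive = true;
  f.outside.clear();
  return true;
}

} // namespace

// [[Rcpp::export]]
List cpp_hull_planes(NumericMatrix pts) {
  int n = pts.nrow();
  if (n < 4) stop("need at least 4 points for a 3-D convex hull");
  std::vector<Vec3> P(n);
  double lo[3] = { R_PosInf, R_PosInf, R_PosInf };
  double hi[3] = { R_NegInf, R_NegInf, R_NegInf };
  for (int i = 0; i < n; ++i) {
    P[i] = { pts(i, 0), pts(i, 1), pts(i, 2) };
    double c[3] = { P[i].x, P[i].y, P[i].z };
    for (int d = 0; d < 3; ++d) {
      if (c[d] < lo[d]) lo[d] = c[d];
      if (c[d] > hi[d]) hi[d] = c[d];
    }
  }
  double scale = std::max({ hi[0] - lo[0], hi[1] - lo[1], hi[2] - lo[2], 1.0 });
  double eps = 1e-9 * scale;

  // initial simplex: farthest pair among axis extremes, then farthest from
  // the line, then farthest from the plane
  int ex[6];
  {
    int mi[3] = { 0, 0, 0 }, ma[3] = { 0, 0, 0 };
    for (int i = 1; i < n; ++i) {
      if (P[i].x < P[mi[0]].x) mi[0] = i;
      if (P[i].x > P[ma[0]].x) ma[0] = i;
      if (P[i].y < P[mi[1]].y) mi[1] = i;
      if (P[i].y > P[ma[1]].y) ma[1] = i;
      if (P[i].z < P[mi[2]].z) mi[2] = i;
      if (P[i].z > P[ma[2]].z) ma[2] = i;
    }
    for (int d = 0; d < 3; ++d) { ex[2 * d] = mi[d]; ex[2 * d + 1] = ma[d]; }
  }
  int i0 = ex[0], i1 = ex[1];
  double best = -1.0;
  for (int a = 0; a < 6; ++a)
    for (int b = a + 1; b < 6; ++b) {
      double d = norm(P[ex[a]] - P[ex[b]]);
      if (d > best) { best = d; i0 = ex[a]; i1 = ex[b]; }
    }
  if (best < eps) stop("degenerate point set: all points coincide");
  int i2 = -1; best = -1.0;
  for (int i = 0; i < n; ++i) {
    double d = norm(cross(P[i] - P[i0], P[i1] - P[i0]));
    if (d > best) { best = d; i2 = i; }
  }
  if (best < eps * norm(P[i1] - P[i0]))
    stop("degenerate point set: all points are collinear");
  Vec3 pn = cross(P[i1] - P[i0], P[i2] - P[i0]);
  pn = pn * (1.0 / norm(pn));
  int i3 = -1; best = -1.0;
  for (int i = 0; i < n; ++i) {
    double d = std::fabs(dot(pn, P[i] - P[i0]));
    if (d > best) { best = d; i3 = i; }
  }
  if (best < eps) stop("degenerate point set: all points are coplanar");

  Vec3 interior = (P[i0] + P[i1] + P[i2] + P[i3]) * 0.25;
  std::vector<Face> faces;
  faces.reserve((size_t)(4 * n));
  int tet[4][3] = { { i0, i1, i2 }, { i0, i1, i3 }, { i0, i2, i3 }, { i1, i2, i3 } };
  for (auto& t : tet) {
    Face f;
    if (!make_face(f, P, t[0], t[1], t[2], interior, eps))
      stop("degenerate initial simplex");
    faces.push_back(f);
  }
  for (int i = 0; i < n; ++i) {
    if (i == i0 || i == i1 || i == i2 || i == i3) continue;
    for (auto& f : faces)
      if (dot(f.n, P[i]) - f.off > eps) { f.outside.push_back(i); break; }
  }

  long long guard = 0;
  while (true) {
    if (++guard > 100LL * n + 1000) stop("convex hull failed to converge");
    int fi = -1;
    for (size_t k = 0; k < faces.size(); ++k)
      if (faces[k].alive && !faces[k].outside.empty()) { fi = (int)k; break; }
    if (fi < 0) break;
    Face& f = faces[fi];
    int p = f.outside[0]; double bd = dot(f.n, P[p]) - f.off;
    for (int q : f.outside) {
      double d = dot(f.n, P[q]) - f.off;
      if (d > bd) { bd = d; p = q; }
    }
    // visible faces and horizon
    std::vector<int> visible;
    for (size_t k = 0; k < faces.size(); ++k)
      if (faces[k].alive && dot(faces[k].n, P[p]) - faces[k].off > eps)
        visible.push_back((int)k);
    std::map<std::pair<int, int>, int> edge_count;
    for (int k : visible) {
      int v[3] = { faces[k].a, faces[k].b, faces[k].c };
      for (int e = 0; e < 3; ++e) {
        int u = v[e], w = v[(e + 1) % 3];
        edge_count[{ u, w }]++;
      }
    }
    std::vector<std::pair<int, int>> horizon;
    for (auto& kv : edge_count) {
      auto rev = std::make_pair(kv.first.second, kv.first.first);
      if (edge_count.find(rev) == edge_count.end()) horizon.push_back(kv.first);
    }
    std::vector<int> orphans;
    for (int k : visible) {
      for (int q : faces[k].outside) if (q != p) orphans.push_back(q);
      faces[k].alive = false;
      faces[k].outside.clear();
    }
    std::vector<int> fresh;
    for (auto& e : horizon) {
      Face nf;
      if (!make_face(nf, P, e.first, e.second, p, interior, eps)) continue;
      faces.push_back(nf);
      fresh.push_back((int)faces.size() - 1);
    }
    for (int q : orphans)
      for (int k : fresh)
        if (dot(faces[k].n, P[q]) - faces[k].off > eps) {
          faces[k].outside.push_back(q);
          break;
        }
  }

  int nf = 0;
  for (auto& f : faces) if (f.alive) ++nf;
  NumericMatrix normals(nf, 3);
  NumericVector offsets(nf);
  IntegerMatrix verts(nf, 3);
  int r = 0;
  for (auto& f : faces) {
    if (!f.alive) continue;
    normals(r, 0) = f.n.x; normals(r, 1) = f.n.y; normals(r, 2) = f.n.z;
    offsets[r] = f.off;
    verts(r, 0) = f.a + 1; verts(r, 1) = f.b + 1; verts(r, 2) = f.c + 1;
    ++r;
  }
  return List::create(_["normals"] = normals, _["offsets"] = offsets,
                      _["vertices"] = verts);
}

// [[Rcpp::export]]
NumericVector cpp_dist_to_hull(NumericMatrix pts, NumericMatrix normals,
                               NumericVector offsets) {
  int n = pts.nrow(), m = normals.nrow();
  if (offsets.size() != m) stop("normals/offsets mismatch");
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    for (int k = 0; k < m; ++k) {
      double d = offsets[k] - (normals(k, 0) * pts(i, 0) +
                               normals(k, 1) * pts(i, 1) +
                               normals(k, 2) * pts(i, 2));
      if (d < best) best = d;
    }
    out[i] = best > 0 ? best : 0.0;   // hull vertices clamp to 0
  }
  return out;
}
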