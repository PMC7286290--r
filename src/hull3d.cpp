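// 3D convex hull (quickhull) returning hull volume, surface area and the
// indices of hull vertices. Used for spheroid shape descriptors.
#include <Rcpp.h>
#include <cmath>
#include <set>
#include <map>
using namespace Rcpp;

struct V3 { double x, y, z; };
static inline V3 sub(const V3 &a, const V3 &b) { return {a.x-b.x, a.y-b.y, a.z-b.z}; }
static inline V3 cross(const V3 &a, const V3 &b) {
  return {a.y*b.z - a.z*b.y, a.z*b.x - a.x*b.z, a.x*b.y - a.y*b.x};
}
static inline double dot(const V3 &a, const V3 &b) { return a.x*b.x + a.y*b.y + a.z*b.z; }
static inline double norm(const V3 &a) { return std::sqrt(dot(a, a)); }

struct Face {
  int a, b, c;          // vertex indices, outward-oriented
  V3 n;                 // unit-ish outward normal
  double off;           // n . p_a
  bool alive;
  std::vector<int> outside;
};

static double face_dist(const Face &f, const V3 &p) { return dot(f.n, p) - f.off; }

static Face make_face(int a, int b, int c, const std::vector<V3> &P, const V3 &inner) {
  Face f; f.a = a; f.b = b; f.c = c; f.alive = true;
  f.n = cross(sub(P[b], P[a]), sub(P[c], P[a]));
  double l = norm(f.n);
  if (l > 0) { f.n.x /= l; f.n.y /= l; f.n.z /= l; }
  f.off = dot(f.n, P[a]);
  if (dot(f.n, inner) - f.off > 0) {  // flip to point away from the interior
    std::swap(f.b, f.c);
    f.n.x = -f.n.x; f.n.y = -f.n.y; f.n.z = -f.n.z;
    f.off = -f.off;
  }
  return f;
}

// [[Rcpp::export]]
List cpp_convhull3d(NumericMatrix pts) {
  int n = pts.nrow();
  std::vector<V3> P(n);
  for (int i = 0; i < n; ++i) P[i] = {pts(i,0), pts(i,1), pts(i,2)};
  if (n < 4)
    return List::create(_["volume"] = 0.0, _["area"] = 0.0,
                        _["vertices"] = IntegerVector(0), _["degenerate"] = true);

  double ext = 0.0;
  for (int d = 0; d < 3; ++d) {
    double lo = R_PosInf, hi = R_NegInf;
    for (int i = 0; i < n; ++i) {
      double v = d == 0 ? P[i].x : (d == 1 ? P[i].y : P[i].z);
      lo = std::min(lo, v); hi = std::max(hi, v);
    }
    ext = std::max(ext, hi - lo);
  }
  double eps = 1e-9 * std::max(ext, 1.0);

  // initial simplex: farthest pair among axis extremes, then line, then plane
  int i0 = 0, i1 = 0;
  {
    double best = -1.0;
    std::vector<int> extreme;
    for (int d = 0; d < 3; ++d) {
      int lo = 0, hi = 0;
      for (int i = 1; i < n; ++i) {
        double v = d == 0 ? P[i].x : (d == 1 ? P[i].y : P[i].z);
        double vl = d == 0 ? P[lo].x : (d == 1 ? P[lo].y : P[lo].z);
        double vh = d == 0 ? P[hi].x : (d == 1 ? P[hi].y : P[hi].z);
        if (v < vl) lo = i;
        if (v > vh) hi = i;
      }
      extreme.push_back(lo); extreme.push_back(hi);
    }
    for (size_t a = 0; a < extreme.size(); ++a)
      for (size_t b = a + 1; b < extreme.size(); ++b) {
        double d = norm(sub(P[extreme[a]], P[extreme[b]]));
        if (d > best) { best = d; i0 = extreme[a]; i1 = extreme[b]; }
      }
    if (best < eps)
      return List::create(_["volume"] = 0.0, _["area"] = 0.0,
                          _["vertices"] = IntegerVector(0), _["degenerate"] = true);
  }
  int i2 = -1;
  {
    double best = -1.0;
    V3 d01 = sub(P[i1], P[i0]);
    for (int i = 0; i < n; ++i) {
      double d = norm(cross(d01, sub(P[i], P[i0]))) / norm(d01);
      if (d > best) { best = d; i2 = i; }
    }
    if (best < eps)
      return List::create(_["volume"] = 0.0, _["area"] = 0.0,
                          _["vertices"] = IntegerVector(0), _["degenerate"] = true);
  }
  int i3 = -1;
  {
    double best = -1.0;
    V3 nrm = cross(sub(P[i1], P[i0]), sub(P[i2], P[i0]));
    double l = norm(nrm);
    for (int i = 0; i < n; ++i) {
      double d = std::fabs(dot(nrm, sub(P[i], P[i0]))) / l;
      if (d > best) { best = d; i3 = i; }
    }
    if (best < eps)
      return List::create(_["volume"] = 0.0, _["area"] = 0.0,
                          _["vertices"] = IntegerVector(0), _["degenerate"] = true);
  }

  V3 inner = {(P[i0].x + P[i1].x + P[i2].x + P[i3].x) / 4.0,
              (P[i0].y + P[i1].y + P[i2].y + P[i3].y) / 4.0,
              (P[i0].z + P[i1].z + P[i2].z + P[i3].z) / 4.0};
  std::vector<Face> faces;
  faces.push_back(make_face(i0, i1, i2, P, inner));
  faces.push_back(make_face(i0, i1, i3, P, inner));
  faces.push_back(make_face(i0, i2, i3, P, inner));
  faces.push_back(make_face(i1, i2, i3, P, inner));

  // assign points to the first face they are outside of
  for (int i = 0; i < n; ++i) {
    if (i == i0 || i == i1 || i == i2 || i == i3) continue;
    for (auto &f : faces)
      if (face_dist(f, P[i]) > eps) { f.outside.push_back(i); break; }
  }

  for (int guard = 0; guard < 100000; ++guard) {
    int fi = -1;
    for (size_t f = 0; f < faces.size(); ++f)
      if (faces[f].alive && !faces[f].outside.empty()) { fi = f; break; }
    if (fi < 0) break;

    // farthest point of this face's outside set
    int far = -1; double best = -1.0;
    for (int i : faces[fi].outside) {
      double d = face_dist(faces[fi], P[i]);
      if (d > best) { best = d; far = i; }
    }
    const V3 &p = P[far];

    // visible faces and their orphaned outside points
    std::vector<int> visible;
    std::vector<int> orphans;
    for (size_t f = 0; f < faces.size(); ++f) {
      if (!faces[f].alive) continue;
      if (face_dist(faces[f], p) > eps) {
        visible.push_back(f);
        for (int i : faces[f].outside) if (i != far) orphans.push_back(i);
        faces[f].outside.clear();
      }
    }
    // horizon: edges used exactly once among visible faces
    std::map<std::pair<int,int>, std::pair<int,int>> edges;  // sorted edge -> oriented
    for (int f : visible) {
      int vs[3][2] = {{faces[f].a, faces[f].b}, {faces[f].b, faces[f].c}, {faces[f].c, faces[f].a}};
      for (auto &e : vs) {
        auto key = std::minmax(e[0], e[1]);
        auto it = edges.find(key);
        if (it == edges.end()) edges[key] = {e[0], e[1]};
        else edges.erase(it);
      }
    }
    for (int f : visible) faces[f].alive = false;

    std::vector<int> fresh;
    for (auto &kv : edges) {
      Face nf = make_face(kv.second.first, kv.second.second, far, P, inner);
      faces.push_back(nf);
      fresh.push_back(faces.size() - 1);
    }
    for (int i : orphans)
      for (int f : fresh)
        if (face_dist(faces[f], P[i]) > eps) { faces[f].outside.push_back(i); break; }
  }

  double vol = 0.0, area = 0.0;
  std::set<int> verts;
  for (auto &f : faces) {
    if (!f.alive) continue;
    V3 u = sub(P[f.b], P[f.a]), v = sub(P[f.c], P[f.a]);
    V3 cr = cross(u, v);
    area += 0.5 * norm(cr);
    // signed tetra volume against the inner point
    V3 a = sub(P[f.a], inner), b = sub(P[f.b], inner), c = sub(P[f.c], inner);
    vol += std::fabs(dot(a, cross(b, c))) / 6.0;
    verts.insert(f.a); verts.insert(f.b); verts.insert(f.c);
  }
  IntegerVector vidx(verts.begin(), verts.end());
  return List::create(_["volume"] = vol, _["area"] = area,
                      _["vertices"] = vidx + 1, _["degenerate"] = false);
}
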