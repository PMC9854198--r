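#include <Rcpp.h>
#include <vector>
#include <map>
#include <cmath>
using namespace Rcpp;

// ---- Digital surface area ------------------------------------------------
//
// Staircase-aware local-slope estimator. Each exposed voxel face contributes
// cos(theta) of its locally estimated surface tilt, so a tilted plane's
// treads and risers together integrate to the true area. The local slope is
// read from the digital surface-height profile over a +-W window; a cliff
// (height jump beyond hmax, e.g. a genuine sharp edge) defers to the opposite
// side of the window, keeping axis-aligned flat faces at weight exactly 1.

static const double CLIFF = -1.0;

// [[Rcpp::export]]
double cpp_surface_area(IntegerVector mask, IntegerVector dim, double spacing,
                        int W = 3, int hmax = 4, double steep = 6.0) {
  const int n[3] = {dim[0], dim[1], dim[2]};
  auto M = [&](int ax, int u, int v, int i, int j, int k) -> bool {
    int idx[3];
    idx[ax] = i; idx[u] = j; idx[v] = k;
    if (idx[0] < 0 || idx[1] < 0 || idx[2] < 0 ||
        idx[0] >= n[0] || idx[1] >= n[1] || idx[2] >= n[2]) return false;
    return mask[idx[0] + (R_xlen_t)n[0] * (idx[1] + (R_xlen_t)n[1] * idx[2])] != 0;
  };
  double A = 0.0;
  static const int DJK[4][2] = {{1,0},{-1,0},{0,1},{0,-1}};
  for (int ax = 0; ax < 3; ++ax) {
    int u = (ax == 0) ? 1 : 0;
    int v = (ax == 2) ? 1 : 2;
    for (int i = -1; i < n[ax]; ++i)
      for (int j = 0; j < n[u]; ++j)
        for (int k = 0; k < n[v]; ++k) {
          const bool lo = M(ax, u, v, i, j, k);
          const bool hi = M(ax, u, v, i + 1, j, k);
          if (lo == hi) continue;
          const int inner = lo ? i : i + 1;
          const int sgn = lo ? 1 : -1;
          double slopes[4];
          for (int d = 0; d < 4; ++d) {
            const int dj = DJK[d][0], dk = DJK[d][1];
            int lvl = inner, t = 0, dh = 0;
            bool cliff = false;
            for (int step = 1; step <= W; ++step) {
              const int jj = j + dj * step, kk = k + dk * step;
              bool found = false;
              int L = 0;
              for (int off = 0; off <= hmax && !found; ++off) {
                for (int s = 0; s < 2; ++s) {
                  const int cand = lvl + (s == 0 ? off : -off);
                  if (M(ax, u, v, cand, jj, kk) &&
                      !M(ax, u, v, cand + sgn, jj, kk)) {
                    L = cand; found = true; break;
                  }
                  if (off == 0) break;
                }
              }
              if (!found) {
                if (step == 1) cliff = true;
                break;
              }
              dh += (L - lvl);
              lvl = L;
              t = step;
            }
            slopes[d] = cliff ? CLIFF : (t > 0 ? std::fabs((double)dh) / t : 0.0);
          }
          auto comb = [&](double sa, double sb) {
            if (sa == CLIFF && sb == CLIFF) return steep;
            if (sa == CLIFF) return sb;
            if (sb == CLIFF) return sa;
            return 0.5 * (sa + sb);
          };
          const double sy = comb(slopes[0], slopes[1]);
          const double sz = comb(slopes[2], slopes[3]);
          A += 1.0 / std::sqrt(1.0 + sy * sy + sz * sz);
        }
  }
  return A * spacing * spacing;
}

// ---- Incremental convex hull (quickhull) ---------------------------------

namespace {

struct HFace {
  int a, b, c;
  double nx, ny, nz, off;
  bool alive;
  std::vector<int> pts;
};

inline void face_plane(const NumericMatrix &P, HFace &f) {
  const double ax = P(f.a,0), ay = P(f.a,1), az = P(f.a,2);
  const double ux = P(f.b,0)-ax, uy = P(f.b,1)-ay, uz = P(f.b,2)-az;
  const double vx = P(f.c,0)-ax, vy = P(f.c,1)-ay, vz = P(f.c,2)-az;
  f.nx = uy*vz - uz*vy;
  f.ny = uz*vx - ux*vz;
  f.nz = ux*vy - uy*vx;
  f.off = f.nx*ax + f.ny*ay + f.nz*az;
}

inline double face_dist(const NumericMatrix &P, const HFace &f, int p) {
  return f.nx*P(p,0) + f.ny*P(p,1) + f.nz*P(p,2) - f.off;
}

} // namespace

// Convex hull of a 3D point cloud: returns volume and hull vertex indices
// (1-based). Degenerate input (coplanar/collinear) yields volume 0 and an
// empty vertex set.
// [[Rcpp::export]]
List cpp_convex_hull(NumericMatrix P) {
  const int npt = P.nrow();
  List degenerate = List::create(_["volume"] = 0.0,
                                 _["vertices"] = IntegerVector(0));
  if (npt < 4) return degenerate;

  // scale for tolerance
  double lo[3] = {R_PosInf, R_PosInf, R_PosInf}, hi[3] = {R_NegInf, R_NegInf, R_NegInf};
  for (int i = 0; i < npt; ++i)
    for (int d = 0; d < 3; ++d) {
      lo[d] = std::min(lo[d], P(i,d));
      hi[d] = std::max(hi[d], P(i,d));
    }
  const double scale = std::max({hi[0]-lo[0], hi[1]-lo[1], hi[2]-lo[2], 1.0});
  const double eps = 1e-9 * scale * scale; // plane offsets scale ~ length^2

  // initial extreme points
  int p0 = 0, p1 = 0;
  double best = -1.0;
  for (int d = 0; d < 3; ++d) {
    int imin = 0, imax = 0;
    for (int i = 1; i < npt; ++i) {
      if (P(i,d) < P(imin,d)) imin = i;
      if (P(i,d) > P(imax,d)) imax = i;
    }
    const double dx = P(imax,0)-P(imin,0), dy = P(imax,1)-P(imin,1), dz = P(imax,2)-P(imin,2);
    const double d2 = dx*dx + dy*dy + dz*dz;
    if (d2 > best) { best = d2; p0 = imin; p1 = imax; }
  }
  if (best <= 0) return degenerate;
  // farthest from line p0-p1
  int p2 = -1; best = eps;
  {
    const double ux = P(p1,0)-P(p0,0), uy = P(p1,1)-P(p0,1), uz = P(p1,2)-P(p0,2);
    for (int i = 0; i < npt; ++i) {
      const double wx = P(i,0)-P(p0,0), wy = P(i,1)-P(p0,1), wz = P(i,2)-P(p0,2);
      const double cx = uy*wz - uz*wy, cy = uz*wx - ux*wz, cz = ux*wy - uy*wx;
      const double d2 = cx*cx + cy*cy + cz*cz;
      if (d2 > best) { best = d2; p2 = i; }
    }
  }
  if (p2 < 0) return degenerate;
  // farthest from plane p0,p1,p2
  HFace base; base.a = p0; base.b = p1; base.c = p2;
  face_plane(P, base);
  int p3 = -1; best = eps;
  for (int i = 0; i < npt; ++i) {
    const double d = std::fabs(face_dist(P, base, i));
    if (d > best) { best = d; p3 = i; }
  }
  if (p3 < 0) return degenerate;

  const double ox = (P(p0,0)+P(p1,0)+P(p2,0)+P(p3,0)) / 4.0;
  const double oy = (P(p0,1)+P(p1,1)+P(p2,1)+P(p3,1)) / 4.0;
  const double oz = (P(p0,2)+P(p1,2)+P(p2,2)+P(p3,2)) / 4.0;

  std::vector<HFace> faces;
  auto add_face = [&](int a, int b, int c) -> int {
    HFace f; f.a = a; f.b = b; f.c = c; f.alive = true;
    face_plane(P, f);
    // orient outward w.r.t. interior point
    if (f.nx*ox + f.ny*oy + f.nz*oz - f.off > 0) {
      std::swap(f.b, f.c);
      face_plane(P, f);
    }
    faces.push_back(f);
    return (int)faces.size() - 1;
  };
  add_face(p0, p1, p2);
  add_face(p0, p1, p3);
  add_face(p0, p2, p3);
  add_face(p1, p2, p3);

  // assign points to faces
  for (int i = 0; i < npt; ++i) {
    if (i == p0 || i == p1 || i == p2 || i == p3) continue;
    for (auto &f : faces)
      if (face_dist(P, f, i) > eps) { f.pts.push_back(i); break; }
  }

  const int max_iter = 20 * npt + 1000;
  for (int iter = 0; iter < max_iter; ++iter) {
    // face with pending points
    int fi = -1;
    for (int t = 0; t < (int)faces.size(); ++t)
      if (faces[t].alive && !faces[t].pts.empty()) { fi = t; break; }
    if (fi < 0) break;
    // farthest point of that face
    int p = -1; double d0 = -1.0;
    for (int q : faces[fi].pts) {
      const double d = face_dist(P, faces[fi], q);
      if (d > d0) { d0 = d; p = q; }
    }
    // visible faces
    std::vector<int> vis;
    for (int t = 0; t < (int)faces.size(); ++t)
      if (faces[t].alive && face_dist(P, faces[t], p) > eps) vis.push_back(t);
    // horizon: directed edges of visible faces whose reverse is not visible
    std::map<std::pair<int,int>, int> edges;
    for (int t : vis) {
      const HFace &f = faces[t];
      const int e[3][2] = {{f.a,f.b},{f.b,f.c},{f.c,f.a}};
      for (int s = 0; s < 3; ++s) edges[{e[s][0], e[s][1]}] = 1;
    }
    std::vector<std::pair<int,int>> horizon;
    for (auto &kv : edges)
      if (!edges.count({kv.first.second, kv.first.first}))
        horizon.push_back(kv.first);
    // orphaned points
    std::vector<int> orphans;
    for (int t : vis) {
      for (int q : faces[t].pts) if (q != p) orphans.push_back(q);
      faces[t].alive = false;
      faces[t].pts.clear();
    }
    // cone of new faces
    std::vector<int> fresh;
    for (auto &e : horizon) fresh.push_back(add_face(e.first, e.second, p));
    for (int q : orphans)
      for (int t : fresh)
        if (face_dist(P, faces[t], q) > eps) { faces[t].pts.push_back(q); break; }
  }

  // volume and vertices
  double vol = 0.0;
  std::vector<bool> used(npt, false);
  for (const auto &f : faces) {
    if (!f.alive) continue;
    const double ax = P(f.a,0)-ox, ay = P(f.a,1)-oy, az = P(f.a,2)-oz;
    const double bx = P(f.b,0)-ox, by = P(f.b,1)-oy, bz = P(f.b,2)-oz;
    const double cx = P(f.c,0)-ox, cy = P(f.c,1)-oy, cz = P(f.c,2)-oz;
    vol += (ax*(by*cz - bz*cy) - ay*(bx*cz - bz*cx) + az*(bx*cy - by*cx)) / 6.0;
    used[f.a] = used[f.b] = used[f.c] = true;
  }
  std::vector<int> verts;
  for (int i = 0; i < npt; ++i) if (used[i]) verts.push_back(i + 1);
  return List::create(_["volume"] = std::fabs(vol),
                      _["vertices"] = wrap(verts));
}
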