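// Low-level geometry kernels: point/triangle distance queries, mesh-mesh
// intersection, inside-outside tests, voxel connected components, marching
// tetrahedra on a Freudenthal cube decomposition, and z-column parity
// voxelization.  All coordinates are millimetres; faces are 0-based here
// (R wrappers convert to/from 1-based).
#include <Rcpp.h>
#include <map>
#include <vector>
#include <queue>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

struct V3 {
  double x, y, z;
  V3() : x(0), y(0), z(0) {}
  V3(double a, double b, double c) : x(a), y(b), z(c) {}
};
static inline V3 operator+(const V3& a, const V3& b) { return V3(a.x + b.x, a.y + b.y, a.z + b.z); }
static inline V3 operator-(const V3& a, const V3& b) { return V3(a.x - b.x, a.y - b.y, a.z - b.z); }
static inline V3 operator*(const V3& a, double s) { return V3(a.x * s, a.y * s, a.z * s); }
static inline double dot(const V3& a, const V3& b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
static inline V3 cross(const V3& a, const V3& b) {
  return V3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x);
}
static inline double norm(const V3& a) { return std::sqrt(dot(a, a)); }

static inline V3 row(const NumericMatrix& m, int i) {
  return V3(m(i, 0), m(i, 1), m(i, 2));
}

// Closest point on triangle (a,b,c) to p.  Ericson, Real-Time Collision
// Detection, 5.1.5.
static V3 closest_on_tri(const V3& p, const V3& a, const V3& b, const V3& c) {
  V3 ab = b - a, ac = c - a, ap = p - a;
  double d1 = dot(ab, ap), d2 = dot(ac, ap);
  if (d1 <= 0.0 && d2 <= 0.0) return a;
  V3 bp = p - b;
  double d3 = dot(ab, bp), d4 = dot(ac, bp);
  if (d3 >= 0.0 && d4 <= d3) return b;
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    return a + ab * v;
  }
  V3 cp = p - c;
  double d5 = dot(ab, cp), d6 = dot(ac, cp);
  if (d6 >= 0.0 && d5 <= d6) return c;
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    return a + ac * w;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    return b + (c - b) * w;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  return a + ab * v + ac * w;
}

// [[Rcpp::export]]
List cpp_closest_points(NumericMatrix Q, NumericMatrix V, IntegerMatrix F) {
  const int nq = Q.nrow(), nf = F.nrow();
  NumericMatrix P(nq, 3);
  IntegerVector face(nq);
  NumericVector dist(nq);
  // Precompute triangle vertices and bounding boxes for cheap rejection.
  std::vector<V3> ta(nf), tb(nf), tc(nf), blo(nf), bhi(nf);
  for (int f = 0; f < nf; ++f) {
    ta[f] = row(V, F(f, 0));
    tb[f] = row(V, F(f, 1));
    tc[f] = row(V, F(f, 2));
    blo[f] = V3(std::min({ta[f].x, tb[f].x, tc[f].x}),
                std::min({ta[f].y, tb[f].y, tc[f].y}),
                std::min({ta[f].z, tb[f].z, tc[f].z}));
    bhi[f] = V3(std::max({ta[f].x, tb[f].x, tc[f].x}),
                std::max({ta[f].y, tb[f].y, tc[f].y}),
                std::max({ta[f].z, tb[f].z, tc[f].z}));
  }
  for (int q = 0; q < nq; ++q) {
    V3 p = row(Q, q);
    double best = R_PosInf;
    int bestf = -1;
    V3 bestp;
    for (int f = 0; f < nf; ++f) {
      // lower bound on distance from box
      double dx = std::max({blo[f].x - p.x, 0.0, p.x - bhi[f].x});
      double dy = std::max({blo[f].y - p.y, 0.0, p.y - bhi[f].y});
      double dz = std::max({blo[f].z - p.z, 0.0, p.z - bhi[f].z});
      if (dx * dx + dy * dy + dz * dz >= best) continue;
      V3 cp = closest_on_tri(p, ta[f], tb[f], tc[f]);
      double d2 = dot(cp - p, cp - p);
      if (d2 < best - 1e-18 || (std::abs(d2 - best) <= 1e-18 && f < bestf)) {
        best = d2;
        bestf = f;
        bestp = cp;
      }
    }
    P(q, 0) = bestp.x; P(q, 1) = bestp.y; P(q, 2) = bestp.z;
    face[q] = bestf;
    dist[q] = std::sqrt(best);
  }
  return List::create(_["point"] = P, _["face"] = face, _["dist"] = dist);
}

// Devillers-Guigue style tri-tri overlap via Moller's interval test.
static bool tri_tri_overlap(const V3& p1, const V3& q1, const V3& r1,
                            const V3& p2, const V3& q2, const V3& r2) {
  const double EPS = 1e-12;
  V3 n1 = cross(q1 - p1, r1 - p1);
  double d1 = -dot(n1, p1);
  double dp2 = dot(n1, p2) + d1, dq2 = dot(n1, q2) + d1, dr2 = dot(n1, r2) + d1;
  if ((dp2 > EPS && dq2 > EPS && dr2 > EPS) || (dp2 < -EPS && dq2 < -EPS && dr2 < -EPS))
    return false;
  V3 n2 = cross(q2 - p2, r2 - p2);
  double d2 = -dot(n2, p2);
  double dp1 = dot(n2, p1) + d2, dq1 = dot(n2, q1) + d2, dr1 = dot(n2, r1) + d2;
  if ((dp1 > EPS && dq1 > EPS && dr1 > EPS) || (dp1 < -EPS && dq1 < -EPS && dr1 < -EPS))
    return false;
  // Coplanar or crossing: project on the dominant axis of the line direction
  V3 dline = cross(n1, n2);
  double adx = std::abs(dline.x), ady = std::abs(dline.y), adz = std::abs(dline.z);
  if (adx + ady + adz < EPS) {
    // (near-)coplanar: conservative AABB overlap answer
    V3 lo1(std::min({p1.x, q1.x, r1.x}), std::min({p1.y, q1.y, r1.y}), std::min({p1.z, q1.z, r1.z}));
    V3 hi1(std::max({p1.x, q1.x, r1.x}), std::max({p1.y, q1.y, r1.y}), std::max({p1.z, q1.z, r1.z}));
    V3 lo2(std::min({p2.x, q2.x, r2.x}), std::min({p2.y, q2.y, r2.y}), std::min({p2.z, q2.z, r2.z}));
    V3 hi2(std::max({p2.x, q2.x, r2.x}), std::max({p2.y, q2.y, r2.y}), std::max({p2.z, q2.z, r2.z}));
    return lo1.x <= hi2.x && lo2.x <= hi1.x && lo1.y <= hi2.y && lo2.y <= hi1.y &&
           lo1.z <= hi2.z && lo2.z <= hi1.z;
  }
  auto interval = [&](const V3& a, const V3& b, const V3& c,
                      double da, double db, double dc, double& t0, double& t1) {
    auto proj = [&](const V3& v) {
      if (adx >= ady && adx >= adz) return v.x;
      if (ady >= adz) return v.y;
      return v.z;
    };
    std::vector<double> ts;
    const V3* vs[3] = {&a, &b, &c};
    double ds[3] = {da, db, dc};
    for (int i = 0; i < 3; ++i) {
      int j = (i + 1) % 3;
      if ((ds[i] > 0 && ds[j] < 0) || (ds[i] < 0 && ds[j] > 0) ||
          std::abs(ds[i]) <= EPS) {
        if (std::abs(ds[i]) <= EPS) {
          ts.push_back(proj(*vs[i]));
        } else {
          double t = ds[i] / (ds[i] - ds[j]);
          V3 pt = *vs[i] + (*vs[j] - *vs[i]) * t;
          ts.push_back(proj(pt));
        }
      }
    }
    if (ts.empty()) return false;
    t0 = *std::min_element(ts.begin(), ts.end());
    t1 = *std::max_element(ts.begin(), ts.end());
    return true;
  };
  double a0, a1, b0, b1;
  if (!interval(p1, q1, r1, dp1, dq1, dr1, a0, a1)) return false;
  if (!interval(p2, q2, r2, dp2, dq2, dr2, b0, b1)) return false;
  return a0 <= b1 + EPS && b0 <= a1 + EPS;
}

// [[Rcpp::export]]
bool cpp_meshes_intersect(NumericMatrix VA, IntegerMatrix FA,
                          NumericMatrix VB, IntegerMatrix FB) {
  const int na = FA.nrow(), nb = FB.nrow();
  std::vector<V3> a0(na), a1(na), a2(na), alo(na), ahi(na);
  for (int f = 0; f < na; ++f) {
    a0[f] = row(VA, FA(f, 0)); a1[f] = row(VA, FA(f, 1)); a2[f] = row(VA, FA(f, 2));
    alo[f] = V3(std::min({a0[f].x, a1[f].x, a2[f].x}), std::min({a0[f].y, a1[f].y, a2[f].y}),
                std::min({a0[f].z, a1[f].z, a2[f].z}));
    ahi[f] = V3(std::max({a0[f].x, a1[f].x, a2[f].x}), std::max({a0[f].y, a1[f].y, a2[f].y}),
                std::max({a0[f].z, a1[f].z, a2[f].z}));
  }
  for (int g = 0; g < nb; ++g) {
    V3 b0 = row(VB, FB(g, 0)), b1 = row(VB, FB(g, 1)), b2 = row(VB, FB(g, 2));
    V3 blo(std::min({b0.x, b1.x, b2.x}), std::min({b0.y, b1.y, b2.y}), std::min({b0.z, b1.z, b2.z}));
    V3 bhi(std::max({b0.x, b1.x, b2.x}), std::max({b0.y, b1.y, b2.y}), std::max({b0.z, b1.z, b2.z}));
    for (int f = 0; f < na; ++f) {
      if (alo[f].x > bhi.x || blo.x > ahi[f].x || alo[f].y > bhi.y ||
          blo.y > ahi[f].y || alo[f].z > bhi.z || blo.z > ahi[f].z)
        continue;
      if (tri_tri_overlap(a0[f], a1[f], a2[f], b0, b1, b2)) return true;
    }
  }
  return false;
}

// Parity inside test with a fixed irrational ray direction (avoids exact
// edge hits for meshes in general position).
// [[Rcpp::export]]
LogicalVector cpp_points_in_mesh(NumericMatrix P, NumericMatrix V, IntegerMatrix F) {
  const int np = P.nrow(), nf = F.nrow();
  V3 dir(0.5773502691896258, 0.6172133998483676, 0.5345224838248488);
  dir = dir * (1.0 / norm(dir));
  LogicalVector inside(np);
  std::vector<V3> ta(nf), tb(nf), tc(nf);
  for (int f = 0; f < nf; ++f) {
    ta[f] = row(V, F(f, 0)); tb[f] = row(V, F(f, 1)); tc[f] = row(V, F(f, 2));
  }
  for (int q = 0; q < np; ++q) {
    V3 o = row(P, q);
    int hits = 0;
    for (int f = 0; f < nf; ++f) {
      // Moller-Trumbore
      V3 e1 = tb[f] - ta[f], e2 = tc[f] - ta[f];
      V3 pv = cross(dir, e2);
      double det = dot(e1, pv);
      if (std::abs(det) < 1e-14) continue;
      double inv = 1.0 / det;
      V3 tv = o - ta[f];
      double u = dot(tv, pv) * inv;
      if (u < 0.0 || u > 1.0) continue;
      V3 qv = cross(tv, e1);
      double v = dot(dir, qv) * inv;
      if (v < 0.0 || u + v > 1.0) continue;
      double t = dot(e2, qv) * inv;
      if (t > 1e-12) ++hits;
    }
    inside[q] = (hits % 2) == 1;
  }
  return inside;
}

// Connected components of a binary 3D mask (column-major nx*ny*nz),
// connectivity 6, 18 or 26.  Returns labels 1..K in discovery order.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims, int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector labels(n, 0);
  std::vector<std::array<int, 3>> offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (m == 0) continue;
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        offs.push_back({dx, dy, dz});
      }
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || labels[s] != 0) continue;
    ++next;
    labels[s] = next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      int cx = cur % nx, cy = (cur / nx) % ny, cz = cur / ((R_xlen_t)nx * ny);
      for (const auto& o : offs) {
        int px = cx + o[0], py = cy + o[1], pz = cz + o[2];
        if (px < 0 || px >= nx || py < 0 || py >= ny || pz < 0 || pz >= nz) continue;
        R_xlen_t idx = px + (R_xlen_t)nx * (py + (R_xlen_t)ny * pz);
        if (mask[idx] && labels[idx] == 0) {
          labels[idx] = next;
          stack.push_back(idx);
        }
      }
    }
  }
  return labels;
}

// Marching tetrahedra on the Freudenthal (6-tet, path-permutation)
// decomposition of each grid cell.  field is column-major nx*ny*nz; output
// vertices are in continuous index space (i,j,k), faces 0-based and wound
// so normals point from inside (field >= iso) to outside.
// [[Rcpp::export]]
List cpp_marching_tets(NumericVector field, IntegerVector dims, double iso) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  auto idx = [&](int i, int j, int k) -> R_xlen_t {
    return i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
  };
  // the 6 permutation paths 000 -> 111
  static const int perms[6][3] = {{0, 1, 2}, {0, 2, 1}, {1, 0, 2},
                                  {1, 2, 0}, {2, 0, 1}, {2, 1, 0}};
  int tets[6][4][3];
  for (int p = 0; p < 6; ++p) {
    int cur[3] = {0, 0, 0};
    tets[p][0][0] = 0; tets[p][0][1] = 0; tets[p][0][2] = 0;
    for (int s = 0; s < 3; ++s) {
      cur[perms[p][s]] = 1;
      for (int a = 0; a < 3; ++a) tets[p][s + 1][a] = cur[a];
    }
  }
  std::map<std::pair<R_xlen_t, R_xlen_t>, int> vmap;
  std::vector<double> vx, vy, vz;
  std::vector<int> tri;
  auto edge_vertex = [&](int ai, int aj, int ak, int bi, int bj, int bk) -> int {
    R_xlen_t a = idx(ai, aj, ak), b = idx(bi, bj, bk);
    if (a > b) { std::swap(a, b); std::swap(ai, bi); std::swap(aj, bj); std::swap(ak, bk); }
    auto key = std::make_pair(a, b);
    auto it = vmap.find(key);
    if (it != vmap.end()) return it->second;
    double fa = field[a], fb = field[b];
    double t = (iso - fa) / (fb - fa);
    if (t < 0) t = 0; if (t > 1) t = 1;
    int id = vx.size();
    vx.push_back(ai + t * (bi - ai));
    vy.push_back(aj + t * (bj - aj));
    vz.push_back(ak + t * (bk - ak));
    vmap[key] = id;
    return id;
  };
  auto emit = [&](int v0, int v1, int v2, const V3& outward) {
    V3 a(vx[v0], vy[v0], vz[v0]), b(vx[v1], vy[v1], vz[v1]), c(vx[v2], vy[v2], vz[v2]);
    V3 nrm = cross(b - a, c - a);
    if (dot(nrm, outward) >= 0) {
      tri.push_back(v0); tri.push_back(v1); tri.push_back(v2);
    } else {
      tri.push_back(v0); tri.push_back(v2); tri.push_back(v1);
    }
  };
  for (int k = 0; k < nz - 1; ++k)
    for (int j = 0; j < ny - 1; ++j)
      for (int i = 0; i < nx - 1; ++i) {
        // quick cube-level reject
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          double f = field[idx(i + (c & 1), j + ((c >> 1) & 1), k + ((c >> 2) & 1))];
          if (f >= iso) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;
        for (int p = 0; p < 6; ++p) {
          int gi[4][3];
          bool ins[4];
          double fv[4];
          for (int v = 0; v < 4; ++v) {
            gi[v][0] = i + tets[p][v][0];
            gi[v][1] = j + tets[p][v][1];
            gi[v][2] = k + tets[p][v][2];
            fv[v] = field[idx(gi[v][0], gi[v][1], gi[v][2])];
            ins[v] = fv[v] >= iso;
          }
          int nin = ins[0] + ins[1] + ins[2] + ins[3];
          if (nin == 0 || nin == 4) continue;
          int in_ids[4], out_ids[4], ni = 0, no = 0;
          for (int v = 0; v < 4; ++v) (ins[v] ? in_ids[ni++] : out_ids[no++]) = v;
          if (nin == 1 || nin == 3) {
            int apex = (nin == 1) ? in_ids[0] : out_ids[0];
            int others[3], m = 0;
            for (int v = 0; v < 4; ++v) if (v != apex) others[m++] = v;
            int e0 = edge_vertex(gi[apex][0], gi[apex][1], gi[apex][2],
                                 gi[others[0]][0], gi[others[0]][1], gi[others[0]][2]);
            int e1 = edge_vertex(gi[apex][0], gi[apex][1], gi[apex][2],
                                 gi[others[1]][0], gi[others[1]][1], gi[others[1]][2]);
            int e2 = edge_vertex(gi[apex][0], gi[apex][1], gi[apex][2],
                                 gi[others[2]][0], gi[others[2]][1], gi[others[2]][2]);
            V3 apexp(gi[apex][0], gi[apex][1], gi[apex][2]);
            V3 ctr((vx[e0] + vx[e1] + vx[e2]) / 3.0, (vy[e0] + vy[e1] + vy[e2]) / 3.0,
                   (vz[e0] + vz[e1] + vz[e2]) / 3.0);
            V3 outward = (nin == 1) ? (ctr - apexp) : (apexp - ctr);
            emit(e0, e1, e2, outward);
          } else {
            int v00 = edge_vertex(gi[in_ids[0]][0], gi[in_ids[0]][1], gi[in_ids[0]][2],
                                  gi[out_ids[0]][0], gi[out_ids[0]][1], gi[out_ids[0]][2]);
            int v01 = edge_vertex(gi[in_ids[0]][0], gi[in_ids[0]][1], gi[in_ids[0]][2],
                                  gi[out_ids[1]][0], gi[out_ids[1]][1], gi[out_ids[1]][2]);
            int v10 = edge_vertex(gi[in_ids[1]][0], gi[in_ids[1]][1], gi[in_ids[1]][2],
                                  gi[out_ids[0]][0], gi[out_ids[0]][1], gi[out_ids[0]][2]);
            int v11 = edge_vertex(gi[in_ids[1]][0], gi[in_ids[1]][1], gi[in_ids[1]][2],
                                  gi[out_ids[1]][0], gi[out_ids[1]][1], gi[out_ids[1]][2]);
            V3 inc((gi[in_ids[0]][0] + gi[in_ids[1]][0]) * 0.5,
                   (gi[in_ids[0]][1] + gi[in_ids[1]][1]) * 0.5,
                   (gi[in_ids[0]][2] + gi[in_ids[1]][2]) * 0.5);
            V3 outc((gi[out_ids[0]][0] + gi[out_ids[1]][0]) * 0.5,
                    (gi[out_ids[0]][1] + gi[out_ids[1]][1]) * 0.5,
                    (gi[out_ids[0]][2] + gi[out_ids[1]][2]) * 0.5);
            V3 outward = outc - inc;
            emit(v00, v01, v11, outward);
            emit(v00, v11, v10, outward);
          }
        }
      }
  int nv = vx.size(), nf = tri.size() / 3;
  NumericMatrix V(nv, 3);
  for (int v = 0; v < nv; ++v) { V(v, 0) = vx[v]; V(v, 1) = vy[v]; V(v, 2) = vz[v]; }
  IntegerMatrix Fm(nf, 3);
  for (int f = 0; f < nf; ++f) {
    Fm(f, 0) = tri[3 * f]; Fm(f, 1) = tri[3 * f + 1]; Fm(f, 2) = tri[3 * f + 2];
  }
  return List::create(_["vertices"] = V, _["faces"] = Fm);
}

// Voxelization by z-column parity: a voxel center is inside if a vertical
// ray through it crosses the mesh an odd number of times below it.
// xs, ys, zs are the world coordinates of voxel centers along each axis.
// [[Rcpp::export]]
LogicalVector cpp_voxelize(NumericMatrix V, IntegerMatrix F,
                           NumericVector xs, NumericVector ys, NumericVector zs) {
  const int nx = xs.size(), ny = ys.size(), nz = zs.size(), nf = F.nrow();
  // tiny deterministic offset avoids rays through vertices/edges
  const double jx = 1e-7, jy = 2.3e-7;
  std::vector<std::vector<double>> crossings((R_xlen_t)nx * ny);
  double x0 = xs[0], y0 = ys[0];
  double dxs = nx > 1 ? xs[1] - xs[0] : 1.0, dys = ny > 1 ? ys[1] - ys[0] : 1.0;
  for (int f = 0; f < nf; ++f) {
    V3 a = row(V, F(f, 0)), b = row(V, F(f, 1)), c = row(V, F(f, 2));
    double xmin = std::min({a.x, b.x, c.x}), xmax = std::max({a.x, b.x, c.x});
    double ymin = std::min({a.y, b.y, c.y}), ymax = std::max({a.y, b.y, c.y});
    int i0 = std::max(0, (int)std::ceil((xmin - x0 - jx) / dxs));
    int i1 = std::min(nx - 1, (int)std::floor((xmax - x0 - jx) / dxs));
    int j0 = std::max(0, (int)std::ceil((ymin - y0 - jy) / dys));
    int j1 = std::min(ny - 1, (int)std::floor((ymax - y0 - jy) / dys));
    double d = (b.x - a.x) * (c.y - a.y) - (c.x - a.x) * (b.y - a.y);
    if (std::abs(d) < 1e-300) continue;  // degenerate in projection
    for (int i = i0; i <= i1; ++i) {
      double px = xs[i] + jx;
      for (int j = j0; j <= j1; ++j) {
        double py = ys[j] + jy;
        double w1 = ((px - a.x) * (c.y - a.y) - (c.x - a.x) * (py - a.y)) / d;
        double w2 = ((b.x - a.x) * (py - a.y) - (px - a.x) * (b.y - a.y)) / d;
        if (w1 < 0 || w2 < 0 || w1 + w2 > 1) continue;
        double zc = a.z + w1 * (b.z - a.z) + w2 * (c.z - a.z);
        crossings[i + (R_xlen_t)nx * j].push_back(zc);
      }
    }
  }
  LogicalVector out((R_xlen_t)nx * ny * nz, false);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      auto& cr = crossings[i + (R_xlen_t)nx * j];
      if (cr.empty()) continue;
      std::sort(cr.begin(), cr.end());
      for (int k = 0; k < nz; ++k) {
        double z = zs[k];
        int below = std::upper_bound(cr.begin(), cr.end(), z) - cr.begin();
        if (below % 2 == 1)
          out[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] = true;
      }
    }
  return out;
}

// Consistent face winding by BFS over shared edges within each connected
// shell; used by repair_orientation().
// [[Rcpp::export]]
IntegerMatrix cpp_orient_faces(IntegerMatrix F) {
  const int nf = F.nrow();
  IntegerMatrix G = clone(F);
  std::map<std::pair<int, int>, std::vector<int>> edge2f;
  for (int f = 0; f < nf; ++f)
    for (int e = 0; e < 3; ++e) {
      int a = G(f, e), b = G(f, (e + 1) % 3);
      edge2f[{std::min(a, b), std::max(a, b)}].push_back(f);
    }
  std::vector<bool> seen(nf, false);
  for (int start = 0; start < nf; ++start) {
    if (seen[start]) continue;
    seen[start] = true;
    std::queue<int> q;
    q.push(start);
    while (!q.empty()) {
      int f = q.front();
      q.pop();
      for (int e = 0; e < 3; ++e) {
        int a = G(f, e), b = G(f, (e + 1) % 3);
        for (int g : edge2f[{std::min(a, b), std::max(a, b)}]) {
          if (g == f || seen[g]) continue;
          bool same_dir = false;
          for (int e2 = 0; e2 < 3; ++e2)
            if (G(g, e2) == a && G(g, (e2 + 1) % 3) == b) same_dir = true;
          if (same_dir) {  // neighbor wound the same way along shared edge -> flip
            int tmp = G(g, 1);
            G(g, 1) = G(g, 2);
            G(g, 2) = tmp;
          }
          seen[g] = true;
          q.push(g);
        }
      }
    }
  }
  return G;
}
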