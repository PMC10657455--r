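#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <algorithm>
#include <vector>
#include <cmath>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// small vector helpers
// ---------------------------------------------------------------------------
struct V3 {
  double x, y, z;
};
static inline V3 v3(double x, double y, double z) { V3 v; v.x = x; v.y = y; v.z = z; return v; }
static inline V3 sub(const V3 &a, const V3 &b) { return v3(a.x - b.x, a.y - b.y, a.z - b.z); }
static inline V3 add(const V3 &a, const V3 &b) { return v3(a.x + b.x, a.y + b.y, a.z + b.z); }
static inline V3 scl(const V3 &a, double s) { return v3(a.x * s, a.y * s, a.z * s); }
static inline double dot(const V3 &a, const V3 &b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
static inline V3 cross(const V3 &a, const V3 &b) {
  return v3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x);
}
static inline double norm2(const V3 &a) { return dot(a, a); }

// Ericson, Real-Time Collision Detection: closest point on triangle abc to p.
static V3 closestPtTriangle(const V3 &p, const V3 &a, const V3 &b, const V3 &c) {
  V3 ab = sub(b, a), ac = sub(c, a), ap = sub(p, a);
  double d1 = dot(ab, ap), d2 = dot(ac, ap);
  if (d1 <= 0.0 && d2 <= 0.0) return a;
  V3 bp = sub(p, b);
  double d3 = dot(ab, bp), d4 = dot(ac, bp);
  if (d3 >= 0.0 && d4 <= d3) return b;
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    return add(a, scl(ab, v));
  }
  V3 cp = sub(p, c);
  double d5 = dot(ab, cp), d6 = dot(ac, cp);
  if (d6 >= 0.0 && d5 <= d6) return c;
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    return add(a, scl(ac, w));
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    return add(b, scl(sub(c, b), w));
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  return add(a, add(scl(ab, v), scl(ac, w)));
}

// ---------------------------------------------------------------------------
// AABB tree over triangles (median split on longest centroid axis)
// ---------------------------------------------------------------------------
struct BVHNode {
  double lo[3], hi[3];
  int left, right;   // children, or -1
  int start, count;  // leaf triangle range into order[]
};

struct BVH {
  std::vector<BVHNode> nodes;
  std::vector<int> order;
  const NumericMatrix *V;
  const IntegerMatrix *F;
  std::vector<V3> a, b, c, centroid;
};

static void bvhNodeBounds(BVH &t, BVHNode &nd) {
  for (int k = 0; k < 3; ++k) { nd.lo[k] = R_PosInf; nd.hi[k] = R_NegInf; }
  for (int i = nd.start; i < nd.start + nd.count; ++i) {
    int f = t.order[i];
    const V3 *vs[3] = { &t.a[f], &t.b[f], &t.c[f] };
    for (int j = 0; j < 3; ++j) {
      const V3 &p = *vs[j];
      nd.lo[0] = std::min(nd.lo[0], p.x); nd.hi[0] = std::max(nd.hi[0], p.x);
      nd.lo[1] = std::min(nd.lo[1], p.y); nd.hi[1] = std::max(nd.hi[1], p.y);
      nd.lo[2] = std::min(nd.lo[2], p.z); nd.hi[2] = std::max(nd.hi[2], p.z);
    }
  }
}

static int bvhBuild(BVH &t, int start, int count) {
  BVHNode nd;
  nd.start = start; nd.count = count; nd.left = nd.right = -1;
  bvhNodeBounds(t, nd);
  int idx = (int)t.nodes.size();
  t.nodes.push_back(nd);
  if (count <= 8) return idx;
  // split on longest extent of centroids
  double clo[3] = { R_PosInf, R_PosInf, R_PosInf }, chi[3] = { R_NegInf, R_NegInf, R_NegInf };
  for (int i = start; i < start + count; ++i) {
    const V3 &p = t.centroid[t.order[i]];
    double pc[3] = { p.x, p.y, p.z };
    for (int k = 0; k < 3; ++k) { clo[k] = std::min(clo[k], pc[k]); chi[k] = std::max(chi[k], pc[k]); }
  }
  int axis = 0;
  double best = chi[0] - clo[0];
  for (int k = 1; k < 3; ++k) if (chi[k] - clo[k] > best) { best = chi[k] - clo[k]; axis = k; }
  if (best <= 0.0) return idx;  // all centroids coincide
  int mid = start + count / 2;
  std::nth_element(t.order.begin() + start, t.order.begin() + mid,
                   t.order.begin() + start + count,
                   [&](int i, int j) {
                     const V3 &pi = t.centroid[i], &pj = t.centroid[j];
                     double vi = axis == 0 ? pi.x : (axis == 1 ? pi.y : pi.z);
                     double vj = axis == 0 ? pj.x : (axis == 1 ? pj.y : pj.z);
                     return vi < vj;
                   });
  int l = bvhBuild(t, start, mid - start);
  int r = bvhBuild(t, mid, start + count - mid);
  t.nodes[idx].left = l;
  t.nodes[idx].right = r;
  t.nodes[idx].count = 0;
  return idx;
}

static inline double boxDist2(const BVHNode &nd, const V3 &p) {
  double d2 = 0.0, pc[3] = { p.x, p.y, p.z };
  for (int k = 0; k < 3; ++k) {
    double d = 0.0;
    if (pc[k] < nd.lo[k]) d = nd.lo[k] - pc[k];
    else if (pc[k] > nd.hi[k]) d = pc[k] - nd.hi[k];
    d2 += d * d;
  }
  return d2;
}

static void bvhQuery(const BVH &t, int node, const V3 &p, double &best2) {
  const BVHNode &nd = t.nodes[node];
  if (boxDist2(nd, p) >= best2) return;
  if (nd.left < 0) {
    for (int i = nd.start; i < nd.start + nd.count; ++i) {
      int f = t.order[i];
      V3 q = closestPtTriangle(p, t.a[f], t.b[f], t.c[f]);
      double d2 = norm2(sub(p, q));
      if (d2 < best2) best2 = d2;
    }
    return;
  }
  double dl = boxDist2(t.nodes[nd.left], p), dr = boxDist2(t.nodes[nd.right], p);
  if (dl < dr) {
    bvhQuery(t, nd.left, p, best2);
    bvhQuery(t, nd.right, p, best2);
  } else {
    bvhQuery(t, nd.right, p, best2);
    bvhQuery(t, nd.left, p, best2);
  }
}

// points: n x 3 query points; V: m x 3 target vertices; F: k x 3 1-based faces.
// Returns the minimum euclidean distance from each point to the target surface.
// [[Rcpp::export]]
NumericVector cpp_surface_distances(NumericMatrix points, NumericMatrix V, IntegerMatrix F) {
  int n = points.nrow(), nf = F.nrow();
  if (nf == 0) stop("target mesh has no faces");
  BVH t;
  t.a.resize(nf); t.b.resize(nf); t.c.resize(nf); t.centroid.resize(nf);
  for (int f = 0; f < nf; ++f) {
    int i = F(f, 0) - 1, j = F(f, 1) - 1, k = F(f, 2) - 1;
    t.a[f] = v3(V(i, 0), V(i, 1), V(i, 2));
    t.b[f] = v3(V(j, 0), V(j, 1), V(j, 2));
    t.c[f] = v3(V(k, 0), V(k, 1), V(k, 2));
    t.centroid[f] = scl(add(t.a[f], add(t.b[f], t.c[f])), 1.0 / 3.0);
  }
  t.order.resize(nf);
  for (int f = 0; f < nf; ++f) t.order[f] = f;
  bvhBuild(t, 0, nf);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    V3 p = v3(points(i, 0), points(i, 1), points(i, 2));
    double best2 = R_PosInf;
    bvhQuery(t, 0, p, best2);
    out[i] = std::sqrt(best2);
  }
  return out;
}

// ray (+x) / triangle intersection, Moller-Trumbore; returns hit with t > 0
static bool rayXHits(const V3 &p, const V3 &a, const V3 &b, const V3 &c) {
  const double EPS = 1e-12;
  V3 dir = v3(1.0, 0.0, 0.0);
  V3 e1 = sub(b, a), e2 = sub(c, a);
  V3 h = cross(dir, e2);
  double det = dot(e1, h);
  if (std::fabs(det) < EPS) return false;
  double inv = 1.0 / det;
  V3 s = sub(p, a);
  double u = dot(s, h) * inv;
  if (u < 0.0 || u > 1.0) return false;
  V3 q = cross(s, e1);
  double v = dot(dir, q) * inv;
  if (v < 0.0 || u + v > 1.0) return false;
  double t = dot(e2, q) * inv;
  return t > EPS;
}

static void bvhRayCount(const BVH &t, int node, const V3 &p, int &hits) {
  const BVHNode &nd = t.nodes[node];
  // prune: the +x ray misses boxes behind the point or offset in y/z
  if (nd.hi[0] < p.x || p.y < nd.lo[1] || p.y > nd.hi[1] ||
      p.z < nd.lo[2] || p.z > nd.hi[2])
    return;
  if (nd.left < 0) {
    for (int i = nd.start; i < nd.start + nd.count; ++i) {
      int f = t.order[i];
      if (rayXHits(p, t.a[f], t.b[f], t.c[f])) ++hits;
    }
    return;
  }
  bvhRayCount(t, nd.left, p, hits);
  bvhRayCount(t, nd.right, p, hits);
}

// Parity test: is each query point inside the closed mesh (V, F)?
// [[Rcpp::export]]
LogicalVector cpp_points_in_mesh(NumericMatrix points, NumericMatrix V,
                                 IntegerMatrix F) {
  int n = points.nrow(), nf = F.nrow();
  if (nf == 0) stop("mesh has no faces");
  BVH t;
  t.a.resize(nf); t.b.resize(nf); t.c.resize(nf); t.centroid.resize(nf);
  for (int f = 0; f < nf; ++f) {
    int i = F(f, 0) - 1, j = F(f, 1) - 1, k = F(f, 2) - 1;
    t.a[f] = v3(V(i, 0), V(i, 1), V(i, 2));
    t.b[f] = v3(V(j, 0), V(j, 1), V(j, 2));
    t.c[f] = v3(V(k, 0), V(k, 1), V(k, 2));
    t.centroid[f] = scl(add(t.a[f], add(t.b[f], t.c[f])), 1.0 / 3.0);
  }
  t.order.resize(nf);
  for (int f = 0; f < nf; ++f) t.order[f] = f;
  bvhBuild(t, 0, nf);
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) {
    V3 p = v3(points(i, 0), points(i, 1), points(i, 2));
    int hits = 0;
    bvhRayCount(t, 0, p, hits);
    out[i] = (hits % 2) == 1;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Marching tetrahedra on a binary scalar grid (level 0.5)
// ---------------------------------------------------------------------------
// mask: binary values at grid samples, linear index z + nz*(y + ny*x)
// (z fastest, matching an R array with dim c(nz, ny, nx)).
// Sample (z,y,x) sits at cartesian (x*h, y*h, z*h).
// Returns list(vertices = n x 3 [x,y,z], faces = m x 3, 1-based) with outward
// orientation (normals point from mask==1 towards mask==0).

// [[Rcpp::export]]
List cpp_marching_tets(IntegerVector mask, int nz, int ny, int nx, double h) {
  const int64_t NG = (int64_t)nz * ny * nx;
  std::unordered_map<uint64_t, int> edgeVert;
  edgeVert.reserve(1024);
  std::vector<double> vx, vy, vz;
  std::vector<int> fa, fb, fc;

  // cube corner offsets in (x,y,z)
  static const int cx[8] = { 0, 1, 1, 0, 0, 1, 1, 0 };
  static const int cy[8] = { 0, 0, 1, 1, 0, 0, 1, 1 };
  static const int cz[8] = { 0, 0, 0, 0, 1, 1, 1, 1 };
  // six tetrahedra around the c0-c6 diagonal (Kuhn decomposition)
  static const int tets[6][4] = {
    { 0, 1, 2, 6 }, { 0, 2, 3, 6 }, { 0, 3, 7, 6 },
    { 0, 7, 4, 6 }, { 0, 4, 5, 6 }, { 0, 5, 1, 6 }
  };

  auto gid = [&](int x, int y, int z) -> int64_t {
    return (int64_t)z + (int64_t)nz * ((int64_t)y + (int64_t)ny * x);
  };
  auto pos = [&](int64_t g) -> V3 {
    int z = (int)(g % nz);
    int64_t r = g / nz;
    int y = (int)(r % ny);
    int x = (int)(r / ny);
    return v3(x * h, y * h, z * h);
  };
  auto getVert = [&](int64_t g1, int64_t g2) -> int {
    uint64_t lo = (uint64_t)std::min(g1, g2), hi = (uint64_t)std::max(g1, g2);
    uint64_t key = lo * (uint64_t)NG + hi;
    auto it = edgeVert.find(key);
    if (it != edgeVert.end()) return it->second;
    V3 p1 = pos(g1), p2 = pos(g2);
    V3 m = scl(add(p1, p2), 0.5);
    int idx = (int)vx.size();
    vx.push_back(m.x); vy.push_back(m.y); vz.push_back(m.z);
    edgeVert[key] = idx;
    return idx;
  };
  auto emit = [&](int i, int j, int k, const V3 &inward) {
    // orient so the normal points away from `inward` (an interior point)
    V3 p1 = v3(vx[i], vy[i], vz[i]);
    V3 p2 = v3(vx[j], vy[j], vz[j]);
    V3 p3 = v3(vx[k], vy[k], vz[k]);
    V3 n = cross(sub(p2, p1), sub(p3, p1));
    V3 cen = scl(add(p1, add(p2, p3)), 1.0 / 3.0);
    if (dot(n, sub(cen, inward)) < 0) std::swap(j, k);
    fa.push_back(i + 1); fb.push_back(j + 1); fc.push_back(k + 1);
  };

  for (int x = 0; x < nx - 1; ++x)
    for (int y = 0; y < ny - 1; ++y)
      for (int z = 0; z < nz - 1; ++z) {
        int64_t g[8];
        int val[8], any = 0, all = 1;
        for (int cnr = 0; cnr < 8; ++cnr) {
          g[cnr] = gid(x + cx[cnr], y + cy[cnr], z + cz[cnr]);
          val[cnr] = mask[g[cnr]] != 0 ? 1 : 0;
          any |= val[cnr];
          all &= val[cnr];
        }
        if (!any || all) continue;
        for (int tt = 0; tt < 6; ++tt) {
          int a = tets[tt][0], b = tets[tt][1], c = tets[tt][2], d = tets[tt][3];
          int inside[4], nin = 0;
          int vv[4] = { a, b, c, d };
          for (int q = 0; q < 4; ++q) if (val[vv[q]]) inside[nin++] = vv[q];
          if (nin == 0 || nin == 4) continue;
          if (nin == 1 || nin == 3) {
            int apex = -1; int others[3]; int no = 0;
            if (nin == 1) {
              apex = inside[0];
              for (int q = 0; q < 4; ++q) if (vv[q] != apex) others[no++] = vv[q];
            } else {
              for (int q = 0; q < 4; ++q) if (!val[vv[q]]) apex = vv[q];
              for (int q = 0; q < 4; ++q) if (vv[q] != apex) others[no++] = vv[q];
            }
            int m1 = getVert(g[apex], g[others[0]]);
            int m2 = getVert(g[apex], g[others[1]]);
            int m3 = getVert(g[apex], g[others[2]]);
            // interior reference: the inside apex (nin==1) or centroid of the
            // three inside corners (nin==3)
            V3 inw;
            if (nin == 1) inw = pos(g[apex]);
            else {
              inw = v3(0, 0, 0);
              for (int q = 0; q < 3; ++q) inw = add(inw, pos(g[others[q]]));
              inw = scl(inw, 1.0 / 3.0);
            }
            emit(m1, m2, m3, inw);
          } else {  // nin == 2
            int in1 = inside[0], in2 = inside[1];
            int out1 = -1, out2 = -1;
            for (int q = 0; q < 4; ++q)
              if (!val[vv[q]]) { if (out1 < 0) out1 = vv[q]; else out2 = vv[q]; }
            int m_ac = getVert(g[in1], g[out1]);
            int m_ad = getVert(g[in1], g[out2]);
            int m_bd = getVert(g[in2], g[out2]);
            int m_bc = getVert(g[in2], g[out1]);
            V3 inw = scl(add(pos(g[in1]), pos(g[in2])), 0.5);
            emit(m_ac, m_ad, m_bd, inw);
            emit(m_ac, m_bd, m_bc, inw);
          }
        }
      }

  int nv = (int)vx.size(), nf2 = (int)fa.size();
  NumericMatrix Vout(nv, 3);
  for (int i = 0; i < nv; ++i) { Vout(i, 0) = vx[i]; Vout(i, 1) = vy[i]; Vout(i, 2) = vz[i]; }
  IntegerMatrix Fout(nf2, 3);
  for (int i = 0; i < nf2; ++i) { Fout(i, 0) = fa[i]; Fout(i, 1) = fb[i]; Fout(i, 2) = fc[i]; }
  return List::create(_["vertices"] = Vout, _["faces"] = Fout);
}

// ---------------------------------------------------------------------------
// Mesh voxelization by +x ray casting with parity counting
// ---------------------------------------------------------------------------
// Samples at (x*h, y*h, z*h) for 0-based indices; returns logical vector with
// linear index z + nz*(y + ny*x) set when the sample is inside the mesh.
// [[Rcpp::export]]
LogicalVector cpp_voxelize(NumericMatrix V, IntegerMatrix F,
                           int nz, int ny, int nx, double h) {
  int nf = F.nrow();
  LogicalVector out((R_xlen_t)nz * ny * nx);
  // bin triangles by their (y,z) bounding rectangle in units of h
  std::vector<std::vector<int>> bins((size_t)ny * nz);
  for (int f = 0; f < nf; ++f) {
    int i = F(f, 0) - 1, j = F(f, 1) - 1, k = F(f, 2) - 1;
    double ylo = std::min({ V(i, 1), V(j, 1), V(k, 1) });
    double yhi = std::max({ V(i, 1), V(j, 1), V(k, 1) });
    double zlo = std::min({ V(i, 2), V(j, 2), V(k, 2) });
    double zhi = std::max({ V(i, 2), V(j, 2), V(k, 2) });
    int y0 = std::max(0, (int)std::ceil(ylo / h)), y1 = std::min(ny - 1, (int)std::floor(yhi / h));
    int z0 = std::max(0, (int)std::ceil(zlo / h)), z1 = std::min(nz - 1, (int)std::floor(zhi / h));
    for (int y = y0; y <= y1; ++y)
      for (int z = z0; z <= z1; ++z)
        bins[(size_t)y * nz + z].push_back(f);
  }
  std::vector<double> xs;
  for (int y = 0; y < ny; ++y)
    for (int z = 0; z < nz; ++z) {
      const std::vector<int> &cand = bins[(size_t)y * nz + z];
      if (cand.empty()) continue;
      double py = y * h, pz = z * h;
      xs.clear();
      for (int f : cand) {
        int i = F(f, 0) - 1, j = F(f, 1) - 1, k = F(f, 2) - 1;
        double y1v = V(i, 1), z1v = V(i, 2), y2v = V(j, 1), z2v = V(j, 2),
               y3v = V(k, 1), z3v = V(k, 2);
        double det = (y2v - y1v) * (z3v - z1v) - (y3v - y1v) * (z2v - z1v);
        if (det == 0.0) continue;  // triangle parallel to the ray
        double b1 = ((py - y1v) * (z3v - z1v) - (y3v - y1v) * (pz - z1v)) / det;
        double b2 = ((y2v - y1v) * (pz - z1v) - (py - y1v) * (z2v - z1v)) / det;
        if (b1 < 0.0 || b2 < 0.0 || b1 + b2 > 1.0) continue;
        double xhit = V(i, 0) + b1 * (V(j, 0) - V(i, 0)) + b2 * (V(k, 0) - V(i, 0));
        xs.push_back(xhit);
      }
      if (xs.empty()) continue;
      std::sort(xs.begin(), xs.end());
      // drop duplicate hits on shared edges/vertices
      std::vector<double> uniq;
      for (double xv : xs)
        if (uniq.empty() || xv - uniq.back() > 1e-9) uniq.push_back(xv);
      size_t ptr = 0;
      for (int x = 0; x < nx; ++x) {
        double px = x * h;
        while (ptr < uniq.size() && uniq[ptr] < px) ++ptr;
        if (ptr % 2 == 1) out[(R_xlen_t)z + (R_xlen_t)nz * (y + (R_xlen_t)ny * x)] = true;
      }
    }
  return out;
}
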