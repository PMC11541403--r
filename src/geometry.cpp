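// Geometry kernel: AABB-tree closest-point / ray queries on triangle meshes,
// signed distance via angle-weighted pseudonormals (Baerentzen & Aanaes),
// regular-grid field sampling and isosurface extraction by marching
// tetrahedra on the Freudenthal 6-tet cube decomposition.
//
// All coordinates are millimetres. Meshes are vertex matrices (n x 3,
// double) plus face matrices (m x 3, 1-based integer from R; converted to
// 0-based internally).

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <cstdint>
#include <limits>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

namespace {

struct V3 {
  double x, y, z;
  V3() : x(0), y(0), z(0) {}
  V3(double a, double b, double c) : x(a), y(b), z(c) {}
};

inline V3 operator+(const V3 &a, const V3 &b) { return V3(a.x + b.x, a.y + b.y, a.z + b.z); }
inline V3 operator-(const V3 &a, const V3 &b) { return V3(a.x - b.x, a.y - b.y, a.z - b.z); }
inline V3 operator*(const V3 &a, double s) { return V3(a.x * s, a.y * s, a.z * s); }
inline double dot(const V3 &a, const V3 &b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
inline V3 cross(const V3 &a, const V3 &b) {
  return V3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x);
}
inline double norm(const V3 &a) { return std::sqrt(dot(a, a)); }
inline V3 normalize(const V3 &a) {
  double n = norm(a);
  return n > 0 ? a * (1.0 / n) : V3(0, 0, 0);
}

// Closest point on triangle abc to p (Ericson, Real-Time Collision
// Detection).  region: 0 face, 1 edge ab, 2 edge bc, 3 edge ca,
// 4 vertex a, 5 vertex b, 6 vertex c.
inline V3 closestPtTri(const V3 &p, const V3 &a, const V3 &b, const V3 &c, int &region) {
  V3 ab = b - a, ac = c - a, ap = p - a;
  double d1 = dot(ab, ap), d2 = dot(ac, ap);
  if (d1 <= 0 && d2 <= 0) { region = 4; return a; }
  V3 bp = p - b;
  double d3 = dot(ab, bp), d4 = dot(ac, bp);
  if (d3 >= 0 && d4 <= d3) { region = 5; return b; }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double v = d1 / (d1 - d3);
    region = 1; return a + ab * v;
  }
  V3 cp = p - c;
  double d5 = dot(ab, cp), d6 = dot(ac, cp);
  if (d6 >= 0 && d5 <= d6) { region = 6; return c; }
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double w = d2 / (d2 - d6);
    region = 3; return a + ac * w;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    region = 2; return b + (c - b) * w;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  region = 0;
  return a + ab * v + ac * w;
}

struct Node {
  V3 lo, hi;
  int left, right;   // child node indices, -1 at leaf
  int start, count;  // triangle range at leaf
};

struct MeshBVH {
  std::vector<V3> V;
  std::vector<int> F;          // 3*m, 0-based
  std::vector<V3> faceN;       // per-face unit normal
  std::vector<V3> edgeN;       // per-face, 3 edge pseudonormals (local edges 01,12,20)
  std::vector<uint8_t> edgeB;  // per-face, 3 boundary flags
  std::vector<V3> vertN;       // angle-weighted vertex pseudonormals
  std::vector<uint8_t> vertB;  // boundary vertex flags
  std::vector<Node> nodes;
  std::vector<int> order;      // triangle permutation for leaves
  bool closed;                 // every edge shared by exactly two faces, opposite winding

  int nf() const { return (int)F.size() / 3; }
};

inline void triBounds(const MeshBVH &M, int t, V3 &lo, V3 &hi) {
  const V3 &a = M.V[M.F[3 * t]], &b = M.V[M.F[3 * t + 1]], &c = M.V[M.F[3 * t + 2]];
  lo.x = std::min(a.x, std::min(b.x, c.x));
  lo.y = std::min(a.y, std::min(b.y, c.y));
  lo.z = std::min(a.z, std::min(b.z, c.z));
  hi.x = std::max(a.x, std::max(b.x, c.x));
  hi.y = std::max(a.y, std::max(b.y, c.y));
  hi.z = std::max(a.z, std::max(b.z, c.z));
}

int buildNode(MeshBVH &M, std::vector<V3> &cent, int start, int count) {
  Node nd;
  nd.lo = V3(1e300, 1e300, 1e300);
  nd.hi = V3(-1e300, -1e300, -1e300);
  for (int i = start; i < start + count; ++i) {
    V3 lo, hi;
    triBounds(M, M.order[i], lo, hi);
    nd.lo.x = std::min(nd.lo.x, lo.x); nd.lo.y = std::min(nd.lo.y, lo.y); nd.lo.z = std::min(nd.lo.z, lo.z);
    nd.hi.x = std::max(nd.hi.x, hi.x); nd.hi.y = std::max(nd.hi.y, hi.y); nd.hi.z = std::max(nd.hi.z, hi.z);
  }
  int idx = (int)M.nodes.size();
  M.nodes.push_back(nd);
  if (count <= 8) {
    M.nodes[idx].left = M.nodes[idx].right = -1;
    M.nodes[idx].start = start;
    M.nodes[idx].count = count;
    return idx;
  }
  V3 ext = nd.hi - nd.lo;
  int axis = 0;
  if (ext.y > ext.x) axis = 1;
  if (ext.z > (axis == 0 ? ext.x : ext.y)) axis = 2;
  int mid = start + count / 2;
  std::nth_element(M.order.begin() + start, M.order.begin() + mid,
                   M.order.begin() + start + count, [&](int a, int b) {
                     const V3 &ca = cent[a], &cb = cent[b];
                     return axis == 0 ? ca.x < cb.x : (axis == 1 ? ca.y < cb.y : ca.z < cb.z);
                   });
  int l = buildNode(M, cent, start, mid - start);
  int r = buildNode(M, cent, mid, start + count - mid);
  M.nodes[idx].left = l;
  M.nodes[idx].right = r;
  M.nodes[idx].start = -1;
  M.nodes[idx].count = 0;
  return idx;
}

inline double boxDist2(const Node &nd, const V3 &p) {
  double dx = std::max(std::max(nd.lo.x - p.x, 0.0), p.x - nd.hi.x);
  double dy = std::max(std::max(nd.lo.y - p.y, 0.0), p.y - nd.hi.y);
  double dz = std::max(std::max(nd.lo.z - p.z, 0.0), p.z - nd.hi.z);
  return dx * dx + dy * dy + dz * dz;
}

struct ClosestHit {
  double d2;
  V3 cp;
  int tri;
  int region;
};

void closestQuery(const MeshBVH &M, const V3 &p, ClosestHit &best) {
  if (M.nodes.empty()) return;
  int stack[128];
  int sp = 0;
  stack[sp++] = 0;
  while (sp > 0) {
    int ni = stack[--sp];
    const Node &nd = M.nodes[ni];
    if (boxDist2(nd, p) >= best.d2) continue;
    if (nd.left < 0) {
      for (int i = nd.start; i < nd.start + nd.count; ++i) {
        int t = M.order[i];
        int reg;
        V3 cp = closestPtTri(p, M.V[M.F[3 * t]], M.V[M.F[3 * t + 1]], M.V[M.F[3 * t + 2]], reg);
        V3 d = p - cp;
        double d2 = dot(d, d);
        if (d2 < best.d2) {
          best.d2 = d2; best.cp = cp; best.tri = t; best.region = reg;
        }
      }
    } else {
      double dl = boxDist2(M.nodes[nd.left], p);
      double dr = boxDist2(M.nodes[nd.right], p);
      // visit nearer child first
      if (dl < dr) {
        if (dr < best.d2) stack[sp++] = nd.right;
        if (dl < best.d2) stack[sp++] = nd.left;
      } else {
        if (dl < best.d2) stack[sp++] = nd.left;
        if (dr < best.d2) stack[sp++] = nd.right;
      }
      if (sp > 120) Rcpp::stop("BVH traversal stack overflow");
    }
  }
}

// Feature pseudonormal and boundary flag for a closest-point result.
inline void featureNormal(const MeshBVH &M, const ClosestHit &h, V3 &n, bool &bnd) {
  int t = h.tri;
  switch (h.region) {
    case 0: n = M.faceN[t]; bnd = false; break;
    case 1: n = M.edgeN[3 * t + 0]; bnd = M.edgeB[3 * t + 0] != 0; break;
    case 2: n = M.edgeN[3 * t + 1]; bnd = M.edgeB[3 * t + 1] != 0; break;
    case 3: n = M.edgeN[3 * t + 2]; bnd = M.edgeB[3 * t + 2] != 0; break;
    case 4: n = M.vertN[M.F[3 * t + 0]]; bnd = M.vertB[M.F[3 * t + 0]] != 0; break;
    case 5: n = M.vertN[M.F[3 * t + 1]]; bnd = M.vertB[M.F[3 * t + 1]] != 0; break;
    default: n = M.vertN[M.F[3 * t + 2]]; bnd = M.vertB[M.F[3 * t + 2]] != 0; break;
  }
}

// Ray / triangle (Moller-Trumbore); returns t or -1.
inline double rayTri(const V3 &o, const V3 &d, const V3 &a, const V3 &b, const V3 &c) {
  const double EPS = 1e-12;
  V3 ab = b - a, ac = c - a;
  V3 pvec = cross(d, ac);
  double det = dot(ab, pvec);
  if (std::fabs(det) < EPS) return -1.0;
  double inv = 1.0 / det;
  V3 tvec = o - a;
  double u = dot(tvec, pvec) * inv;
  if (u < -1e-9 || u > 1 + 1e-9) return -1.0;
  V3 qvec = cross(tvec, ab);
  double v = dot(d, qvec) * inv;
  if (v < -1e-9 || u + v > 1 + 1e-9) return -1.0;
  return dot(ac, qvec) * inv;
}

inline bool rayBox(const Node &nd, const V3 &o, const V3 &inv, double tmax) {
  double t0 = 0.0, t1 = tmax;
  double a = (nd.lo.x - o.x) * inv.x, b = (nd.hi.x - o.x) * inv.x;
  if (a > b) std::swap(a, b);
  t0 = std::max(t0, a); t1 = std::min(t1, b);
  a = (nd.lo.y - o.y) * inv.y; b = (nd.hi.y - o.y) * inv.y;
  if (a > b) std::swap(a, b);
  t0 = std::max(t0, a); t1 = std::min(t1, b);
  a = (nd.lo.z - o.z) * inv.z; b = (nd.hi.z - o.z) * inv.z;
  if (a > b) std::swap(a, b);
  t0 = std::max(t0, a); t1 = std::min(t1, b);
  return t0 <= t1;
}

void rayQuery(const MeshBVH &M, const V3 &o, const V3 &d, double tmin, double &bestT, int &bestTri) {
  if (M.nodes.empty()) return;
  V3 inv(1.0 / (d.x != 0 ? d.x : 1e-300), 1.0 / (d.y != 0 ? d.y : 1e-300),
         1.0 / (d.z != 0 ? d.z : 1e-300));
  int stack[128];
  int sp = 0;
  stack[sp++] = 0;
  while (sp > 0) {
    int ni = stack[--sp];
    const Node &nd = M.nodes[ni];
    if (!rayBox(nd, o, inv, bestT)) continue;
    if (nd.left < 0) {
      for (int i = nd.start; i < nd.start + nd.count; ++i) {
        int t = M.order[i];
        double tt = rayTri(o, d, M.V[M.F[3 * t]], M.V[M.F[3 * t + 1]], M.V[M.F[3 * t + 2]]);
        if (tt > tmin && tt < bestT) { bestT = tt; bestTri = t; }
      }
    } else {
      stack[sp++] = nd.left;
      stack[sp++] = nd.right;
      if (sp > 120) Rcpp::stop("BVH ray stack overflow");
    }
  }
}

MeshBVH *buildMesh(const NumericMatrix &Vm, const IntegerMatrix &Fm) {
  MeshBVH *M = new MeshBVH();
  int nv = Vm.nrow(), nf = Fm.nrow();
  M->V.resize(nv);
  for (int i = 0; i < nv; ++i) M->V[i] = V3(Vm(i, 0), Vm(i, 1), Vm(i, 2));
  M->F.resize(3 * nf);
  for (int i = 0; i < nf; ++i)
    for (int k = 0; k < 3; ++k) {
      int idx = Fm(i, k) - 1;
      if (idx < 0 || idx >= nv) { delete M; Rcpp::stop("face index out of range"); }
      M->F[3 * i + k] = idx;
    }
  // face normals and angle-weighted vertex normals
  M->faceN.resize(nf);
  M->vertN.assign(nv, V3());
  M->vertB.assign(nv, 0);
  for (int t = 0; t < nf; ++t) {
    const V3 &a = M->V[M->F[3 * t]], &b = M->V[M->F[3 * t + 1]], &c = M->V[M->F[3 * t + 2]];
    V3 n = cross(b - a, c - a);
    M->faceN[t] = normalize(n);
    // angle weights
    V3 e0 = normalize(b - a), e1 = normalize(c - b), e2 = normalize(a - c);
    double wa = std::acos(std::max(-1.0, std::min(1.0, dot(e0, V3() - e2))));
    double wb = std::acos(std::max(-1.0, std::min(1.0, dot(e1, V3() - e0))));
    double wc = std::acos(std::max(-1.0, std::min(1.0, dot(e2, V3() - e1))));
    M->vertN[M->F[3 * t]] = M->vertN[M->F[3 * t]] + M->faceN[t] * wa;
    M->vertN[M->F[3 * t + 1]] = M->vertN[M->F[3 * t + 1]] + M->faceN[t] * wb;
    M->vertN[M->F[3 * t + 2]] = M->vertN[M->F[3 * t + 2]] + M->faceN[t] * wc;
  }
  for (int i = 0; i < nv; ++i) M->vertN[i] = normalize(M->vertN[i]);
  // edge pseudonormals via undirected edge map
  std::unordered_map<uint64_t, std::pair<V3, int>> emap;
  emap.reserve(3 * nf);
  auto ekey = [](int a, int b) {
    uint64_t lo = (uint64_t)std::min(a, b), hi = (uint64_t)std::max(a, b);
    return (hi << 32) | lo;
  };
  for (int t = 0; t < nf; ++t)
    for (int k = 0; k < 3; ++k) {
      int a = M->F[3 * t + k], b = M->F[3 * t + (k + 1) % 3];
      auto &e = emap[ekey(a, b)];
      e.first = e.first + M->faceN[t];
      e.second += 1;
    }
  M->edgeN.resize(3 * nf);
  M->edgeB.resize(3 * nf);
  bool closed = nf > 0;
  for (auto &kv : emap)
    if (kv.second.second != 2) closed = false;
  for (int t = 0; t < nf; ++t)
    for (int k = 0; k < 3; ++k) {
      int a = M->F[3 * t + k], b = M->F[3 * t + (k + 1) % 3];
      auto &e = emap[ekey(a, b)];
      M->edgeN[3 * t + k] = normalize(e.first);
      M->edgeB[3 * t + k] = e.second == 1 ? 1 : 0;
      if (e.second == 1) {
        M->vertB[a] = 1;
        M->vertB[b] = 1;
      }
    }
  M->closed = closed;
  // BVH
  M->order.resize(nf);
  std::vector<V3> cent(nf);
  for (int t = 0; t < nf; ++t) {
    M->order[t] = t;
    cent[t] = (M->V[M->F[3 * t]] + M->V[M->F[3 * t + 1]] + M->V[M->F[3 * t + 2]]) * (1.0 / 3.0);
  }
  if (nf > 0) buildNode(*M, cent, 0, nf);
  return M;
}

inline double signedValue(const MeshBVH &M, const V3 &p, bool &bndOut) {
  ClosestHit h;
  h.d2 = std::numeric_limits<double>::infinity();
  h.tri = -1;
  closestQuery(M, p, h);
  if (h.tri < 0) { bndOut = false; return std::numeric_limits<double>::infinity(); }
  double d = std::sqrt(h.d2);
  V3 n;
  bool bnd;
  featureNormal(M, h, n, bnd);
  bndOut = bnd;
  double s = dot(p - h.cp, n);
  return s >= 0 ? d : -d;
}

}  // namespace

// ---- exported interface ----------------------------------------------------

// [[Rcpp::export]]
SEXP cpp_bvh_build(NumericMatrix V, IntegerMatrix F) {
  MeshBVH *M = buildMesh(V, F);
  XPtr<MeshBVH> p(M, true);
  return p;
}

// [[Rcpp::export]]
bool cpp_bvh_closed(SEXP ptr) {
  XPtr<MeshBVH> M(ptr);
  return M->closed;
}

// [[Rcpp::export]]
List cpp_closest(SEXP ptr, NumericMatrix Q) {
  XPtr<MeshBVH> M(ptr);
  int n = Q.nrow();
  NumericVector dist(n), sgn(n);
  LogicalVector bnd(n);
  IntegerVector tri(n);
  NumericMatrix P(n, 3), N(n, 3);
  for (int i = 0; i < n; ++i) {
    V3 p(Q(i, 0), Q(i, 1), Q(i, 2));
    ClosestHit h;
    h.d2 = std::numeric_limits<double>::infinity();
    h.tri = -1;
    closestQuery(*M, p, h);
    if (h.tri < 0) {
      dist[i] = NA_REAL; sgn[i] = NA_REAL; bnd[i] = NA_LOGICAL; tri[i] = NA_INTEGER;
      continue;
    }
    dist[i] = std::sqrt(h.d2);
    V3 nrm;
    bool b;
    featureNormal(*M, h, nrm, b);
    double s = dot(p - h.cp, nrm);
    sgn[i] = s >= 0 ? 1.0 : -1.0;
    bnd[i] = b;
    tri[i] = h.tri + 1;
    P(i, 0) = h.cp.x; P(i, 1) = h.cp.y; P(i, 2) = h.cp.z;
    N(i, 0) = nrm.x; N(i, 1) = nrm.y; N(i, 2) = nrm.z;
  }
  return List::create(_["distance"] = dist, _["sign"] = sgn, _["boundary"] = bnd,
                      _["tri"] = tri, _["point"] = P, _["normal"] = N);
}

// [[Rcpp::export]]
List cpp_grid_field(SEXP ptr, NumericVector origin, NumericVector spacing,
                    IntegerVector dims) {
  XPtr<MeshBVH> M(ptr);
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t total = (R_xlen_t)nx * ny * nz;
  NumericVector out(total);
  LogicalVector bnd(total);
  R_xlen_t idx = 0;
  for (int iz = 0; iz < nz; ++iz) {
    double z = origin[2] + iz * spacing[2];
    for (int iy = 0; iy < ny; ++iy) {
      double y = origin[1] + iy * spacing[1];
      for (int ix = 0; ix < nx; ++ix) {
        double x = origin[0] + ix * spacing[0];
        bool b;
        out[idx] = signedValue(*M, V3(x, y, z), b);
        bnd[idx] = b;
        ++idx;
      }
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["field"] = out, _["boundary"] = bnd);
}

// [[Rcpp::export]]
List cpp_raycast(SEXP ptr, NumericMatrix O, NumericMatrix D, double tmin) {
  XPtr<MeshBVH> M(ptr);
  int n = O.nrow();
  NumericVector tt(n);
  IntegerVector tri(n);
  for (int i = 0; i < n; ++i) {
    V3 o(O(i, 0), O(i, 1), O(i, 2)), d(D(i, 0), D(i, 1), D(i, 2));
    double bestT = std::numeric_limits<double>::infinity();
    int bestTri = -1;
    rayQuery(*M, o, d, tmin, bestT, bestTri);
    tt[i] = bestT;
    tri[i] = bestTri < 0 ? NA_INTEGER : bestTri + 1;
  }
  return List::create(_["t"] = tt, _["tri"] = tri);
}

// [[Rcpp::export]]
List cpp_edge_audit(IntegerMatrix F, int nV) {
  // Counts undirected edge multiplicities and winding consistency.
  std::unordered_map<uint64_t, std::pair<int, int>> emap;  // (fwd count, bwd count)
  int nf = F.nrow();
  emap.reserve(3 * nf);
  for (int t = 0; t < nf; ++t)
    for (int k = 0; k < 3; ++k) {
      int a = F(t, k) - 1, b = F(t, (k + 1) % 3) - 1;
      if (a < 0 || b < 0 || a >= nV || b >= nV) stop("face index out of range");
      uint64_t lo = (uint64_t)std::min(a, b), hi = (uint64_t)std::max(a, b);
      uint64_t key = (hi << 32) | lo;
      auto &e = emap[key];
      if (a < b) e.first += 1; else e.second += 1;
    }
  int nBoundary = 0, nNonManifold = 0, nMismatched = 0;
  for (auto &kv : emap) {
    int tot = kv.second.first + kv.second.second;
    if (tot == 1) ++nBoundary;
    else if (tot > 2) ++nNonManifold;
    else if (kv.second.first != 1 || kv.second.second != 1) ++nMismatched;
  }
  return List::create(_["n_edges"] = (int)emap.size(), _["n_boundary"] = nBoundary,
                      _["n_nonmanifold"] = nNonManifold, _["n_mismatched"] = nMismatched);
}

// [[Rcpp::export]]
List cpp_marching_tets(NumericVector field, IntegerVector dims, NumericVector origin,
                       NumericVector spacing, double iso) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  auto nodeId = [&](int ix, int iy, int iz) {
    return (uint64_t)ix + (uint64_t)nx * ((uint64_t)iy + (uint64_t)ny * (uint64_t)iz);
  };
  auto nodeVal = [&](uint64_t id) { return field[(R_xlen_t)id]; };
  auto nodePos = [&](uint64_t id) {
    int ix = (int)(id % nx);
    int iy = (int)((id / nx) % ny);
    int iz = (int)(id / ((uint64_t)nx * ny));
    return V3(origin[0] + ix * spacing[0], origin[1] + iy * spacing[1], origin[2] + iz * spacing[2]);
  };

  std::unordered_map<uint64_t, int> evert;  // packed (min,max) node pair -> vertex index
  evert.reserve(1 << 16);
  std::vector<double> VX;  // flat xyz
  std::vector<int> FI;     // flat 0-based triples

  auto crossing = [&](uint64_t a, uint64_t b) -> int {
    uint64_t lo = std::min(a, b), hi = std::max(a, b);
    // node counts stay below 2^32, so the packed pair key is exact
    uint64_t exact = (lo << 32) | (hi & 0xffffffffu);
    auto it = evert.find(exact);
    if (it != evert.end()) return it->second;
    double va = nodeVal(lo), vb = nodeVal(hi);
    double t = (iso - va) / (vb - va);
    if (t < 0) t = 0;
    if (t > 1) t = 1;
    V3 pa = nodePos(lo), pb = nodePos(hi);
    V3 p = pa + (pb - pa) * t;
    int idx = (int)(VX.size() / 3);
    VX.push_back(p.x); VX.push_back(p.y); VX.push_back(p.z);
    evert[exact] = idx;
    return idx;
  };

  auto orient = [&](uint64_t a, uint64_t b, uint64_t c, uint64_t d) {
    V3 pa = nodePos(a), pb = nodePos(b), pc = nodePos(c), pd = nodePos(d);
    V3 u = pb - pa, v = pc - pa, w = pd - pa;
    return dot(cross(u, v), w);
  };

  // Freudenthal tets of the unit cube (corner bit order x,y,z)
  static const int TETS[6][4] = {{0, 1, 3, 7}, {0, 1, 5, 7}, {0, 2, 3, 7},
                                 {0, 2, 6, 7}, {0, 4, 5, 7}, {0, 4, 6, 7}};

  uint64_t corner[8];
  double val[8];
  for (int iz = 0; iz < nz - 1; ++iz) {
    for (int iy = 0; iy < ny - 1; ++iy) {
      for (int ix = 0; ix < nx - 1; ++ix) {
        bool anyIn = false, anyOut = false;
        for (int k = 0; k < 8; ++k) {
          corner[k] = nodeId(ix + (k & 1), iy + ((k >> 1) & 1), iz + ((k >> 2) & 1));
          val[k] = nodeVal(corner[k]);
          if (val[k] < iso) anyIn = true; else anyOut = true;
        }
        if (!anyIn || !anyOut) continue;
        for (int tt = 0; tt < 6; ++tt) {
          uint64_t tv[4];
          double fv[4];
          int in[4], nin = 0, out[4], nout = 0;
          for (int k = 0; k < 4; ++k) {
            tv[k] = corner[TETS[tt][k]];
            fv[k] = val[TETS[tt][k]];
            if (fv[k] < iso) in[nin++] = k; else out[nout++] = k;
          }
          if (nin == 0 || nin == 4) continue;
          if (nin == 1) {
            uint64_t A = tv[in[0]];
            uint64_t B = tv[out[0]], C = tv[out[1]], D = tv[out[2]];
            if (orient(A, B, C, D) < 0) std::swap(C, D);
            int p1 = crossing(A, B), p2 = crossing(A, C), p3 = crossing(A, D);
            FI.push_back(p1); FI.push_back(p2); FI.push_back(p3);
          } else if (nin == 3) {
            uint64_t O = tv[out[0]];
            uint64_t I1 = tv[in[0]], I2 = tv[in[1]], I3 = tv[in[2]];
            if (orient(O, I1, I2, I3) < 0) std::swap(I2, I3);
            int q1 = crossing(O, I1), q2 = crossing(O, I2), q3 = crossing(O, I3);
            FI.push_back(q1); FI.push_back(q3); FI.push_back(q2);
          } else {
            uint64_t A = tv[in[0]], B = tv[in[1]];
            uint64_t C = tv[out[0]], D = tv[out[1]];
            if (orient(A, B, C, D) < 0) std::swap(C, D);
            int pac = crossing(A, C), pad = crossing(A, D);
            int pbc = crossing(B, C), pbd = crossing(B, D);
            FI.push_back(pac); FI.push_back(pbd); FI.push_back(pbc);
            FI.push_back(pac); FI.push_back(pad); FI.push_back(pbd);
          }
        }
      }
    }
    Rcpp::checkUserInterrupt();
  }

  int nvOut = (int)(VX.size() / 3), nfOut = (int)(FI.size() / 3);
  NumericMatrix Vout(nvOut, 3);
  for (int i = 0; i < nvOut; ++i) {
    Vout(i, 0) = VX[3 * i]; Vout(i, 1) = VX[3 * i + 1]; Vout(i, 2) = VX[3 * i + 2];
  }
  IntegerMatrix Fout(nfOut, 3);
  for (int i = 0; i < nfOut; ++i) {
    Fout(i, 0) = FI[3 * i] + 1; Fout(i, 1) = FI[3 * i + 1] + 1; Fout(i, 2) = FI[3 * i + 2] + 1;
  }
  return List::create(_["vertices"] = Vout, _["faces"] = Fout);
}
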