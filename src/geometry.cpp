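// Geometric kernels: exact point-to-triangle closest-point queries (uniform-grid
// accelerated), marching-tetrahedra isosurface extraction, solid voxelization by
// parity ray casting, trilinear volume sampling, separable Gaussian smoothing.
#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
#include <unordered_map>
#include <algorithm>
#include <limits>

using namespace Rcpp;

struct Vec3 {
  double x, y, z;
  Vec3() : x(0), y(0), z(0) {}
  Vec3(double x_, double y_, double z_) : x(x_), y(y_), z(z_) {}
  Vec3 operator-(const Vec3& o) const { return Vec3(x - o.x, y - o.y, z - o.z); }
  Vec3 operator+(const Vec3& o) const { return Vec3(x + o.x, y + o.y, z + o.z); }
  Vec3 operator*(double s) const { return Vec3(x * s, y * s, z * s); }
};
static inline double dot(const Vec3& a, const Vec3& b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}
static inline Vec3 cross(const Vec3& a, const Vec3& b) {
  return Vec3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x);
}
static inline double norm2(const Vec3& a) { return dot(a, a); }

// Closest point on triangle abc to p (Ericson, Real-Time Collision Detection).
static Vec3 closestPtTri(const Vec3& p, const Vec3& a, const Vec3& b, const Vec3& c) {
  Vec3 ab = b - a, ac = c - a, ap = p - a;
  double d1 = dot(ab, ap), d2 = dot(ac, ap);
  if (d1 <= 0.0 && d2 <= 0.0) return a;
  Vec3 bp = p - b;
  double d3 = dot(ab, bp), d4 = dot(ac, bp);
  if (d3 >= 0.0 && d4 <= d3) return b;
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    return a + ab * v;
  }
  Vec3 cp = p - c;
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
NumericMatrix cpp_closest_points_brute(NumericMatrix Q, NumericMatrix V, IntegerMatrix F) {
  int nq = Q.nrow(), nf = F.nrow();
  NumericMatrix out(nq, 5);
  for (int q = 0; q < nq; ++q) {
    Vec3 p(Q(q, 0), Q(q, 1), Q(q, 2));
    double best = std::numeric_limits<double>::infinity();
    Vec3 bestPt;
    int bestFace = -1;
    for (int f = 0; f < nf; ++f) {
      Vec3 a(V(F(f, 0) - 1, 0), V(F(f, 0) - 1, 1), V(F(f, 0) - 1, 2));
      Vec3 b(V(F(f, 1) - 1, 0), V(F(f, 1) - 1, 1), V(F(f, 1) - 1, 2));
      Vec3 c(V(F(f, 2) - 1, 0), V(F(f, 2) - 1, 1), V(F(f, 2) - 1, 2));
      Vec3 cp = closestPtTri(p, a, b, c);
      double d2 = norm2(p - cp);
      if (d2 < best) { best = d2; bestPt = cp; bestFace = f; }
    }
    out(q, 0) = std::sqrt(best);
    out(q, 1) = bestPt.x; out(q, 2) = bestPt.y; out(q, 3) = bestPt.z;
    out(q, 4) = bestFace + 1;
  }
  return out;
}

struct FaceGrid {
  double ox, oy, oz, h;
  int gx, gy, gz;
  std::vector<std::vector<int> > cells;
  int clampi(int v, int lo, int hi) const { return v < lo ? lo : (v > hi ? hi : v); }
  int idx(int i, int j, int k) const { return (k * gy + j) * gx + i; }
};

static void buildGrid(FaceGrid& g, const NumericMatrix& V, const IntegerMatrix& F) {
  int nf = F.nrow();
  double mn[3], mx[3];
  for (int d = 0; d < 3; ++d) { mn[d] = R_PosInf; mx[d] = R_NegInf; }
  for (int i = 0; i < V.nrow(); ++i)
    for (int d = 0; d < 3; ++d) {
      if (V(i, d) < mn[d]) mn[d] = V(i, d);
      if (V(i, d) > mx[d]) mx[d] = V(i, d);
    }
  double ext = std::max(mx[0] - mn[0], std::max(mx[1] - mn[1], mx[2] - mn[2]));
  if (ext <= 0) ext = 1.0;
  // target ~ nf^(1/3) cells per axis, capped
  int target = (int)std::ceil(std::pow((double)std::max(nf, 1), 1.0 / 3.0));
  target = std::max(4, std::min(96, target));
  g.h = ext / target;
  g.ox = mn[0] - 1e-9; g.oy = mn[1] - 1e-9; g.oz = mn[2] - 1e-9;
  g.gx = std::max(1, (int)std::ceil((mx[0] - mn[0]) / g.h) + 1);
  g.gy = std::max(1, (int)std::ceil((mx[1] - mn[1]) / g.h) + 1);
  g.gz = std::max(1, (int)std::ceil((mx[2] - mn[2]) / g.h) + 1);
  g.cells.assign((size_t)g.gx * g.gy * g.gz, std::vector<int>());
  for (int f = 0; f < nf; ++f) {
    double fmn[3] = {R_PosInf, R_PosInf, R_PosInf};
    double fmx[3] = {R_NegInf, R_NegInf, R_NegInf};
    for (int c = 0; c < 3; ++c) {
      int vi = F(f, c) - 1;
      for (int d = 0; d < 3; ++d) {
        if (V(vi, d) < fmn[d]) fmn[d] = V(vi, d);
        if (V(vi, d) > fmx[d]) fmx[d] = V(vi, d);
      }
    }
    int i0 = g.clampi((int)((fmn[0] - g.ox) / g.h), 0, g.gx - 1);
    int i1 = g.clampi((int)((fmx[0] - g.ox) / g.h), 0, g.gx - 1);
    int j0 = g.clampi((int)((fmn[1] - g.oy) / g.h), 0, g.gy - 1);
    int j1 = g.clampi((int)((fmx[1] - g.oy) / g.h), 0, g.gy - 1);
    int k0 = g.clampi((int)((fmn[2] - g.oz) / g.h), 0, g.gz - 1);
    int k1 = g.clampi((int)((fmx[2] - g.oz) / g.h), 0, g.gz - 1);
    for (int k = k0; k <= k1; ++k)
      for (int j = j0; j <= j1; ++j)
        for (int i = i0; i <= i1; ++i)
          g.cells[g.idx(i, j, k)].push_back(f);
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_closest_points(NumericMatrix Q, NumericMatrix V, IntegerMatrix F) {
  int nq = Q.nrow(), nf = F.nrow();
  if (nf == 0) stop("mesh has no faces");
  if (nf < 64) return cpp_closest_points_brute(Q, V, F);
  FaceGrid g;
  buildGrid(g, V, F);
  NumericMatrix out(nq, 5);
  std::vector<int> stamp((size_t)nf, -1);
  int maxRing = g.gx + g.gy + g.gz + 2;
  for (int q = 0; q < nq; ++q) {
    Vec3 p(Q(q, 0), Q(q, 1), Q(q, 2));
    int ci = g.clampi((int)((p.x - g.ox) / g.h), 0, g.gx - 1);
    int cj = g.clampi((int)((p.y - g.oy) / g.h), 0, g.gy - 1);
    int ck = g.clampi((int)((p.z - g.oz) / g.h), 0, g.gz - 1);
    // distance from p to its (clamped) cell: nonzero when p outside the grid bbox
    double cx0 = g.ox + ci * g.h, cy0 = g.oy + cj * g.h, cz0 = g.oz + ck * g.h;
    double dx = std::max(0.0, std::max(cx0 - p.x, p.x - (cx0 + g.h)));
    double dy = std::max(0.0, std::max(cy0 - p.y, p.y - (cy0 + g.h)));
    double dz = std::max(0.0, std::max(cz0 - p.z, p.z - (cz0 + g.h)));
    double clampDist = std::sqrt(dx * dx + dy * dy + dz * dz);
    double best = std::numeric_limits<double>::infinity();
    Vec3 bestPt;
    int bestFace = -1;
    for (int r = 0; r <= maxRing; ++r) {
      // conservative lower bound on distance to any face first seen in ring r
      double lb = (r - 1) * g.h - clampDist;
      if (bestFace >= 0 && std::sqrt(best) <= lb) break;
      bool any = false;
      for (int k = ck - r; k <= ck + r; ++k) {
        if (k < 0 || k >= g.gz) continue;
        for (int j = cj - r; j <= cj + r; ++j) {
          if (j < 0 || j >= g.gy) continue;
          for (int i = ci - r; i <= ci + r; ++i) {
            if (i < 0 || i >= g.gx) continue;
            // shell only
            if (r > 0 && std::abs(i - ci) != r && std::abs(j - cj) != r &&
                std::abs(k - ck) != r) continue;
            const std::vector<int>& fs = g.cells[g.idx(i, j, k)];
            for (size_t t = 0; t < fs.size(); ++t) {
              int f = fs[t];
              if (stamp[f] == q) continue;
              stamp[f] = q;
              any = true;
              Vec3 a(V(F(f, 0) - 1, 0), V(F(f, 0) - 1, 1), V(F(f, 0) - 1, 2));
              Vec3 b(V(F(f, 1) - 1, 0), V(F(f, 1) - 1, 1), V(F(f, 1) - 1, 2));
              Vec3 c(V(F(f, 2) - 1, 0), V(F(f, 2) - 1, 1), V(F(f, 2) - 1, 2));
              Vec3 cp = closestPtTri(p, a, b, c);
              double d2 = norm2(p - cp);
              if (d2 < best) { best = d2; bestPt = cp; bestFace = f; }
            }
          }
        }
      }
      (void)any;
    }
    out(q, 0) = std::sqrt(best);
    out(q, 1) = bestPt.x; out(q, 2) = bestPt.y; out(q, 3) = bestPt.z;
    out(q, 4) = bestFace + 1;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Marching tetrahedra
// ---------------------------------------------------------------------------

// 6-tetrahedron decomposition of the unit cube sharing diagonal c0-c7.
static const int TETS[6][4] = {
  {0, 5, 1, 7}, {0, 1, 3, 7}, {0, 3, 2, 7},
  {0, 2, 6, 7}, {0, 6, 4, 7}, {0, 4, 5, 7}
};

// [[Rcpp::export]]
List cpp_marching_tets(NumericVector vol, int nx, int ny, int nz, double iso,
                       NumericVector spacing, NumericVector origin) {
  std::vector<double> VX, VY, VZ;
  std::vector<int> FA, FB, FC;
  std::unordered_map<uint64_t, int> edgeVert;
  uint64_t N = (uint64_t)nx * ny * nz;
  (void)N;
  std::vector<int> nodeId(8);
  double cv[8];
  Vec3 cpos[8];

  #define NODE(i, j, k) ((int)((size_t)(k) * ny * nx + (size_t)(j) * nx + (i)))
  #define VAL(id) vol[id]

  for (int k = 0; k < nz - 1; ++k) {
    for (int j = 0; j < ny - 1; ++j) {
      for (int i = 0; i < nx - 1; ++i) {
        bool anyIn = false, anyOut = false;
        for (int c = 0; c < 8; ++c) {
          int di = c & 1, dj = (c >> 1) & 1, dk = (c >> 2) & 1;
          nodeId[c] = NODE(i + di, j + dj, k + dk);
          cv[c] = VAL(nodeId[c]);
          cpos[c] = Vec3(origin[0] + (i + di) * spacing[0],
                         origin[1] + (j + dj) * spacing[1],
                         origin[2] + (k + dk) * spacing[2]);
          if (cv[c] > iso) anyIn = true; else anyOut = true;
        }
        if (!anyIn || !anyOut) continue;
        for (int t = 0; t < 6; ++t) {
          int tc[4] = {TETS[t][0], TETS[t][1], TETS[t][2], TETS[t][3]};
          int in[4], nin = 0;
          for (int c = 0; c < 4; ++c) {
            in[c] = cv[tc[c]] > iso ? 1 : 0;
            nin += in[c];
          }
          if (nin == 0 || nin == 4) continue;
          // interpolated vertex on edge (a,b), deduplicated globally
          int ev[4], ne = 0;
          int insideCorners[4], nic = 0;
          for (int c = 0; c < 4; ++c) if (in[c]) insideCorners[nic++] = tc[c];
          // collect crossed edges of the tet
          static const int TE[6][2] = {{0,1},{0,2},{0,3},{1,2},{1,3},{2,3}};
          for (int e = 0; e < 6; ++e) {
            int a = TE[e][0], b = TE[e][1];
            if (in[a] == in[b]) continue;
            int ga = nodeId[tc[a]], gb = nodeId[tc[b]];
            uint64_t key = ga < gb
              ? ((uint64_t)ga << 32) | (uint64_t)gb
              : ((uint64_t)gb << 32) | (uint64_t)ga;
            std::unordered_map<uint64_t, int>::iterator it = edgeVert.find(key);
            int vid;
            if (it == edgeVert.end()) {
              double va = cv[tc[a]], vb = cv[tc[b]];
              double tt = (iso - va) / (vb - va);
              if (tt < 0) tt = 0; if (tt > 1) tt = 1;
              Vec3 pa = cpos[tc[a]], pb = cpos[tc[b]];
              Vec3 p = pa + (pb - pa) * tt;
              VX.push_back(p.x); VY.push_back(p.y); VZ.push_back(p.z);
              vid = (int)VX.size() - 1;
              edgeVert[key] = vid;
            } else vid = it->second;
            ev[ne++] = vid;
          }
          // orient each triangle so its normal points away from the inside
          Vec3 insideC(0, 0, 0);
          for (int c = 0; c < nic; ++c) insideC = insideC + cpos[insideCorners[c]];
          insideC = insideC * (1.0 / nic);
          int tris[2][3];
          int ntri = 0;
          if (ne == 3) {
            tris[0][0] = ev[0]; tris[0][1] = ev[1]; tris[0][2] = ev[2];
            ntri = 1;
          } else if (ne == 4) {
            // order the quad: edges come from 2-in/2-out; ev order from TE scan is
            // (i0-o0, i0-o1, i1-o0, i1-o1) -> quad ev0, ev1, ev3, ev2
            tris[0][0] = ev[0]; tris[0][1] = ev[1]; tris[0][2] = ev[3];
            tris[1][0] = ev[0]; tris[1][1] = ev[3]; tris[1][2] = ev[2];
            ntri = 2;
          }
          for (int ti = 0; ti < ntri; ++ti) {
            int a = tris[ti][0], b = tris[ti][1], c = tris[ti][2];
            Vec3 pa(VX[a], VY[a], VZ[a]), pb(VX[b], VY[b], VZ[b]), pc(VX[c], VY[c], VZ[c]);
            Vec3 n = cross(pb - pa, pc - pa);
            Vec3 triC = (pa + pb + pc) * (1.0 / 3.0);
            if (dot(n, triC - insideC) < 0) { int tmp = b; b = c; c = tmp; }
            FA.push_back(a + 1); FB.push_back(b + 1); FC.push_back(c + 1);
          }
        }
      }
    }
  }
  #undef NODE
  #undef VAL
  int nv = (int)VX.size(), nfc = (int)FA.size();
  NumericMatrix Vout(nv, 3);
  for (int i = 0; i < nv; ++i) { Vout(i, 0) = VX[i]; Vout(i, 1) = VY[i]; Vout(i, 2) = VZ[i]; }
  IntegerMatrix Fout(nfc, 3);
  for (int i = 0; i < nfc; ++i) { Fout(i, 0) = FA[i]; Fout(i, 1) = FB[i]; Fout(i, 2) = FC[i]; }
  return List::create(Named("vertices") = Vout, Named("faces") = Fout);
}

// ---------------------------------------------------------------------------
// Solid voxelization: parity ray casting along +z through voxel centers
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_voxelize(NumericMatrix V, IntegerMatrix F,
                           NumericVector origin, NumericVector spacing,
                           IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int nf = F.nrow();
  IntegerVector occ((size_t)nx * ny * nz);
  // deterministic sub-voxel ray offsets avoid hitting triangle edges exactly
  double epsx = 1e-4 * spacing[0] * 0.57435;
  double epsy = 1e-4 * spacing[1] * 0.31831;
  std::vector<std::vector<double> > cols((size_t)nx * ny);
  for (int f = 0; f < nf; ++f) {
    int i0v = F(f, 0) - 1, i1v = F(f, 1) - 1, i2v = F(f, 2) - 1;
    double ax = V(i0v, 0), ay = V(i0v, 1), az = V(i0v, 2);
    double bx = V(i1v, 0), by = V(i1v, 1), bz = V(i1v, 2);
    double cx = V(i2v, 0), cy = V(i2v, 1), cz = V(i2v, 2);
    double xmn = std::min(ax, std::min(bx, cx)), xmx = std::max(ax, std::max(bx, cx));
    double ymn = std::min(ay, std::min(by, cy)), ymx = std::max(ay, std::max(by, cy));
    int i0 = (int)std::ceil((xmn - origin[0] - epsx) / spacing[0]);
    int i1 = (int)std::floor((xmx - origin[0] - epsx) / spacing[0]);
    int j0 = (int)std::ceil((ymn - origin[1] - epsy) / spacing[1]);
    int j1 = (int)std::floor((ymx - origin[1] - epsy) / spacing[1]);
    i0 = std::max(i0, 0); i1 = std::min(i1, nx - 1);
    j0 = std::max(j0, 0); j1 = std::min(j1, ny - 1);
    for (int j = j0; j <= j1; ++j) {
      double py = origin[1] + j * spacing[1] + epsy;
      for (int i = i0; i <= i1; ++i) {
        double px = origin[0] + i * spacing[0] + epsx;
        // 2D barycentric in xy
        double v0x = bx - ax, v0y = by - ay;
        double v1x = cx - ax, v1y = cy - ay;
        double v2x = px - ax, v2y = py - ay;
        double den = v0x * v1y - v1x * v0y;
        if (std::abs(den) < 1e-14) continue; // triangle vertical in z
        double u = (v2x * v1y - v1x * v2y) / den;
        double w = (v0x * v2y - v2x * v0y) / den;
        if (u < 0 || w < 0 || u + w > 1) continue;
        double zhit = az + u * (bz - az) + w * (cz - az);
        cols[(size_t)j * nx + i].push_back(zhit);
      }
    }
  }
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      std::vector<double>& zs = cols[(size_t)j * nx + i];
      if (zs.empty()) continue;
      std::sort(zs.begin(), zs.end());
      if (zs.size() % 2 != 0) continue; // numerically degenerate column
      for (size_t s = 0; s + 1 < zs.size(); s += 2) {
        int k0 = (int)std::ceil((zs[s] - origin[2]) / spacing[2]);
        int k1 = (int)std::floor((zs[s + 1] - origin[2]) / spacing[2]);
        k0 = std::max(k0, 0); k1 = std::min(k1, nz - 1);
        for (int k = k0; k <= k1; ++k)
          occ[((size_t)k * ny + j) * nx + i] = 1;
      }
    }
  }
  return occ;
}

// ---------------------------------------------------------------------------
// Trilinear sampling at continuous 0-based voxel-index coordinates
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_trilinear(NumericVector vol, IntegerVector dims, NumericMatrix pts) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n = pts.nrow();
  NumericVector out(n);
  for (int q = 0; q < n; ++q) {
    double x = pts(q, 0), y = pts(q, 1), z = pts(q, 2);
    if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1) {
      out[q] = NA_REAL;
      continue;
    }
    int i = std::min((int)x, nx - 2), j = std::min((int)y, ny - 2), k = std::min((int)z, nz - 2);
    if (nx == 1) i = 0; if (ny == 1) j = 0; if (nz == 1) k = 0;
    double fx = x - i, fy = y - j, fz = z - k;
    #define AT(ii, jj, kk) vol[((size_t)(kk) * ny + (jj)) * nx + (ii)]
    double c00 = AT(i, j, k) * (1 - fx) + AT(i + 1, j, k) * fx;
    double c10 = AT(i, j + 1, k) * (1 - fx) + AT(i + 1, j + 1, k) * fx;
    double c01 = AT(i, j, k + 1) * (1 - fx) + AT(i + 1, j, k + 1) * fx;
    double c11 = AT(i, j + 1, k + 1) * (1 - fx) + AT(i + 1, j + 1, k + 1) * fx;
    #undef AT
    double c0 = c00 * (1 - fy) + c10 * fy;
    double c1 = c01 * (1 - fy) + c11 * fy;
    out[q] = c0 * (1 - fz) + c1 * fz;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Separable Gaussian smoothing (sigma in voxels, reflective boundary)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_blur3d(NumericVector vol, IntegerVector dims, double sigma) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  if (sigma <= 0) return clone(vol);
  int rad = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> ker(2 * rad + 1);
  double s = 0;
  for (int t = -rad; t <= rad; ++t) {
    ker[t + rad] = std::exp(-0.5 * t * t / (sigma * sigma));
    s += ker[t + rad];
  }
  for (size_t t = 0; t < ker.size(); ++t) ker[t] /= s;
  size_t n = (size_t)nx * ny * nz;
  std::vector<double> a(vol.begin(), vol.end()), b(n);
  #define IDX(i, j, k) (((size_t)(k) * ny + (j)) * nx + (i))
  #define REFL(v, lim) ((v) < 0 ? -(v) - 1 : ((v) >= (lim) ? 2 * (lim) - (v) - 1 : (v)))
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double acc = 0;
        for (int t = -rad; t <= rad; ++t)
          acc += ker[t + rad] * a[IDX(REFL(i + t, nx), j, k)];
        b[IDX(i, j, k)] = acc;
      }
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double acc = 0;
        for (int t = -rad; t <= rad; ++t)
          acc += ker[t + rad] * b[IDX(i, REFL(j + t, ny), k)];
        a[IDX(i, j, k)] = acc;
      }
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double acc = 0;
        for (int t = -rad; t <= rad; ++t)
          acc += ker[t + rad] * a[IDX(i, j, REFL(k + t, nz))];
        b[IDX(i, j, k)] = acc;
      }
  #undef IDX
  #undef REFL
  return NumericVector(b.begin(), b.end());
}
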