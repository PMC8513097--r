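// Low-level 3D voxel primitives: connected-component labelling,
// topology-preserving thinning, convex hull, iso-surface area,
// separable Gaussian smoothing, and capsule/ellipsoid voxelization.
// R arrays are column-major with dim = (nx, ny, nz); x is the fastest axis.
#include <Rcpp.h>
#include <vector>
#include <array>
#include <map>
#include <queue>
#include <algorithm>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

static inline long long idx3(int i, int j, int k, int nx, int ny) {
  return (long long)i + (long long)nx * ((long long)j + (long long)ny * k);
}

// ---------------------------------------------------------------- labelling

// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dim, int connectivity) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  long long n = (long long)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<std::array<int,3>> offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (!dx && !dy && !dz) continue;
        int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        offs.push_back({dx, dy, dz});
      }
  int cur = 0;
  std::vector<long long> stack;
  for (long long s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++cur;
    lab[s] = cur;
    stack.push_back(s);
    while (!stack.empty()) {
      long long v = stack.back(); stack.pop_back();
      int k = (int)(v / ((long long)nx * ny));
      int rem = (int)(v % ((long long)nx * ny));
      int j = rem / nx, i = rem % nx;
      for (const auto &o : offs) {
        int ii = i + o[0], jj = j + o[1], kk = k + o[2];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
        long long w = idx3(ii, jj, kk, nx, ny);
        if (mask[w] && !lab[w]) { lab[w] = cur; stack.push_back(w); }
      }
    }
  }
  lab.attr("dim") = dim;
  lab.attr("n_components") = cur;
  return lab;
}

// ------------------------------------------------------------------ thinning

// 3x3x3 neighbourhood as 27 flags, position p = (dx+1) + 3*(dy+1) + 9*(dz+1),
// centre at p = 13. A foreground voxel is "simple" (deletable without changing
// topology) iff the foreground in its 26-neighbourhood is one 26-connected
// component AND the background in its 18-neighbourhood is one 6-connected
// component touching a face neighbour (Bertrand & Malandain characterization).
static bool simple_point(const uint8_t *cube) {
  static const int DX[27] = {-1,0,1,-1,0,1,-1,0,1,-1,0,1,-1,0,1,-1,0,1,-1,0,1,-1,0,1,-1,0,1};
  static const int DY[27] = {-1,-1,-1,0,0,0,1,1,1,-1,-1,-1,0,0,0,1,1,1,-1,-1,-1,0,0,0,1,1,1};
  static const int DZ[27] = {-1,-1,-1,-1,-1,-1,-1,-1,-1,0,0,0,0,0,0,0,0,0,1,1,1,1,1,1,1,1,1};

  // C*: 26-components of foreground among the 26 neighbours
  bool vis[27] = {false};
  int ncomp = 0;
  for (int s = 0; s < 27; ++s) {
    if (s == 13 || !cube[s] || vis[s]) continue;
    if (++ncomp > 1) return false;
    int st[27]; int top = 0; st[top++] = s; vis[s] = true;
    while (top) {
      int v = st[--top];
      for (int w = 0; w < 27; ++w) {
        if (w == 13 || !cube[w] || vis[w]) continue;
        if (std::abs(DX[v]-DX[w]) <= 1 && std::abs(DY[v]-DY[w]) <= 1 &&
            std::abs(DZ[v]-DZ[w]) <= 1) { vis[w] = true; st[top++] = w; }
      }
    }
  }
  if (ncomp != 1) return false;

  // T-bar: 6-components of background within the 18-neighbourhood that
  // include a face neighbour of the centre
  bool vis2[27] = {false};
  int ncomp2 = 0;
  for (int s = 0; s < 27; ++s) {
    int m = std::abs(DX[s]) + std::abs(DY[s]) + std::abs(DZ[s]);
    if (m != 1) continue;            // seed only from face neighbours
    if (cube[s] || vis2[s]) continue;
    if (++ncomp2 > 1) return false;
    int st[27]; int top = 0; st[top++] = s; vis2[s] = true;
    while (top) {
      int v = st[--top];
      for (int w = 0; w < 27; ++w) {
        if (w == 13 || cube[w] || vis2[w]) continue;
        int mw = std::abs(DX[w]) + std::abs(DY[w]) + std::abs(DZ[w]);
        if (mw > 2) continue;        // 18-neighbourhood only
        if (std::abs(DX[v]-DX[w]) + std::abs(DY[v]-DY[w]) + std::abs(DZ[v]-DZ[w]) == 1) {
          vis2[w] = true; st[top++] = w;
        }
      }
    }
  }
  return ncomp2 == 1;
}

// 1D lower-envelope pass of the Felzenszwalb-Huttenlocher squared EDT
static void edt1d(const std::vector<double> &f, std::vector<double> &d,
                  double step, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int q = 0;
  v[0] = 0; z[0] = -1e300; z[1] = 1e300;
  for (int i = 1; i < n; ++i) {
    double s;
    while (true) {
      double xi = i * step, xq = v[q] * step;
      s = ((f[i] + xi * xi) - (f[v[q]] + xq * xq)) / (2 * xi - 2 * xq);
      if (s <= z[q]) { --q; } else break;
    }
    ++q;
    v[q] = i; z[q] = s; z[q + 1] = 1e300;
  }
  q = 0;
  for (int i = 0; i < n; ++i) {
    double xi = i * step;
    while (z[q + 1] < xi) ++q;
    double dx = xi - v[q] * step;
    d[i] = dx * dx + f[v[q]];
  }
}

// anisotropic squared Euclidean distance to background, foreground voxels only
static std::vector<double> edt3d(const std::vector<uint8_t> &img,
                                 int nx, int ny, int nz,
                                 double sx, double sy, double sz) {
  long long n = (long long)nx * ny * nz;
  std::vector<double> d(n);
  for (long long s = 0; s < n; ++s) d[s] = img[s] ? 1e300 : 0.0;
  std::vector<double> f, g;
  // x pass
  f.resize(nx); g.resize(nx);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      long long base = idx3(0, j, k, nx, ny);
      for (int i = 0; i < nx; ++i) f[i] = d[base + i];
      edt1d(f, g, sx, nx);
      for (int i = 0; i < nx; ++i) d[base + i] = g[i];
    }
  // y pass
  f.resize(ny); g.resize(ny);
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      for (int j = 0; j < ny; ++j) f[j] = d[idx3(i, j, k, nx, ny)];
      edt1d(f, g, sy, ny);
      for (int j = 0; j < ny; ++j) d[idx3(i, j, k, nx, ny)] = g[j];
    }
  // z pass
  f.resize(nz); g.resize(nz);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      for (int k = 0; k < nz; ++k) f[k] = d[idx3(i, j, k, nx, ny)];
      edt1d(f, g, sz, nz);
      for (int k = 0; k < nz; ++k) d[idx3(i, j, k, nx, ny)] = g[k];
    }
  return d;
}

// Distance-ordered homotopic thinning to a curve skeleton: foreground
// voxels are deleted in increasing order of their Euclidean distance to the
// background (anisotropic voxel spacing respected), a voxel being deletable
// only while it is a simple point and not a curve end point. Topology
// (component and loop counts) is preserved exactly; deletion order makes
// the surviving curves run along the distance ridge, i.e. the centerline.
// [[Rcpp::export]]
LogicalVector cpp_thin3d(LogicalVector mask, IntegerVector dim, NumericVector spacing) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  long long n = (long long)nx * ny * nz;
  std::vector<uint8_t> img(n);
  for (long long s = 0; s < n; ++s) img[s] = mask[s] ? 1 : 0;
  std::vector<double> dist = edt3d(img, nx, ny, nz, spacing[0], spacing[1], spacing[2]);

  auto get = [&](int i, int j, int k) -> uint8_t {
    if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) return 0;
    return img[idx3(i, j, k, nx, ny)];
  };
  auto nbcount = [&](int i, int j, int k) {
    int c = 0;
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (!dx && !dy && !dz) continue;
          c += get(i + dx, j + dy, k + dz);
        }
    return c;
  };
  uint8_t cube[27];
  auto fill_cube = [&](int i, int j, int k) {
    int p = 0;
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx)
          cube[p++] = get(i + dx, j + dy, k + dz);
  };

  typedef std::pair<double, long long> Item;   // (distance, index); min-heap
  std::priority_queue<Item, std::vector<Item>, std::greater<Item>> heap;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        long long v = idx3(i, j, k, nx, ny);
        if (!img[v]) continue;
        bool border = false;
        for (int dz = -1; dz <= 1 && !border; ++dz)
          for (int dy = -1; dy <= 1 && !border; ++dy)
            for (int dx = -1; dx <= 1 && !border; ++dx)
              if ((dx || dy || dz) && !get(i + dx, j + dy, k + dz)) border = true;
        if (border) heap.push({dist[v], v});
      }
  while (!heap.empty()) {
    long long v = heap.top().second;
    heap.pop();
    if (!img[v]) continue;
    int k = (int)(v / ((long long)nx * ny));
    int rem = (int)(v % ((long long)nx * ny));
    int j = rem / nx, i = rem % nx;
    if (nbcount(i, j, k) < 2) continue;        // protect curve end points
    fill_cube(i, j, k);
    if (!simple_point(cube)) continue;         // re-pushed if a neighbor dies
    img[v] = 0;
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (!dx && !dy && !dz) continue;
          int ii = i + dx, jj = j + dy, kk = k + dz;
          if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
          long long w = idx3(ii, jj, kk, nx, ny);
          if (img[w]) heap.push({dist[w], w});
        }
  }
  LogicalVector out(n);
  for (long long s = 0; s < n; ++s) out[s] = img[s] != 0;
  out.attr("dim") = dim;
  return out;
}

// --------------------------------------------------------------- convex hull

struct Face { int a, b, c; double nx, ny, nz, d; bool alive; };

static inline void face_plane(Face &f, const NumericMatrix &P) {
  double ax = P(f.a,0), ay = P(f.a,1), az = P(f.a,2);
  double ux = P(f.b,0)-ax, uy = P(f.b,1)-ay, uz = P(f.b,2)-az;
  double vx = P(f.c,0)-ax, vy = P(f.c,1)-ay, vz = P(f.c,2)-az;
  f.nx = uy*vz - uz*vy; f.ny = uz*vx - ux*vz; f.nz = ux*vy - uy*vx;
  f.d = f.nx*ax + f.ny*ay + f.nz*az;
}

// Incremental 3D convex hull. Returns volume (µm^3 if points are µm),
// centroid, surface area and a degeneracy flag.
// [[Rcpp::export]]
List cpp_chull3d(NumericMatrix P) {
  int n = P.nrow();
  List deg = List::create(_["volume"] = 0.0, _["centroid"] = NumericVector(3),
                          _["area"] = 0.0, _["degenerate"] = true);
  if (n < 4) return deg;

  double lo[3], hi[3];
  for (int c = 0; c < 3; ++c) { lo[c] = hi[c] = P(0,c); }
  for (int i = 1; i < n; ++i)
    for (int c = 0; c < 3; ++c) {
      if (P(i,c) < lo[c]) lo[c] = P(i,c);
      if (P(i,c) > hi[c]) hi[c] = P(i,c);
    }
  double scale = std::sqrt((hi[0]-lo[0])*(hi[0]-lo[0]) + (hi[1]-lo[1])*(hi[1]-lo[1]) +
                           (hi[2]-lo[2])*(hi[2]-lo[2]));
  if (scale <= 0) return deg;
  double eps = 1e-9 * scale;

  // initial tetrahedron from extreme points
  int i0 = 0;
  for (int i = 1; i < n; ++i) if (P(i,0) < P(i0,0)) i0 = i;
  int i1 = -1; double best = -1;
  for (int i = 0; i < n; ++i) {
    double dx = P(i,0)-P(i0,0), dy = P(i,1)-P(i0,1), dz = P(i,2)-P(i0,2);
    double d2 = dx*dx + dy*dy + dz*dz;
    if (d2 > best) { best = d2; i1 = i; }
  }
  if (best <= eps*eps) return deg;
  double ux = P(i1,0)-P(i0,0), uy = P(i1,1)-P(i0,1), uz = P(i1,2)-P(i0,2);
  int i2 = -1; best = -1;
  for (int i = 0; i < n; ++i) {
    double wx = P(i,0)-P(i0,0), wy = P(i,1)-P(i0,1), wz = P(i,2)-P(i0,2);
    double cx = uy*wz - uz*wy, cy = uz*wx - ux*wz, cz = ux*wy - uy*wx;
    double d2 = cx*cx + cy*cy + cz*cz;
    if (d2 > best) { best = d2; i2 = i; }
  }
  if (best <= eps*eps) return deg;
  Face f0 = {i0, i1, i2, 0,0,0,0, true};
  face_plane(f0, P);
  double nn = std::sqrt(f0.nx*f0.nx + f0.ny*f0.ny + f0.nz*f0.nz);
  int i3 = -1; best = -1;
  for (int i = 0; i < n; ++i) {
    double dist = std::fabs(f0.nx*P(i,0) + f0.ny*P(i,1) + f0.nz*P(i,2) - f0.d) / nn;
    if (dist > best) { best = dist; i3 = i; }
  }
  if (best <= eps) return deg;

  double ox = (P(i0,0)+P(i1,0)+P(i2,0)+P(i3,0)) / 4.0;
  double oy = (P(i0,1)+P(i1,1)+P(i2,1)+P(i3,1)) / 4.0;
  double oz = (P(i0,2)+P(i1,2)+P(i2,2)+P(i3,2)) / 4.0;

  std::vector<Face> faces;
  auto add_face = [&](int a, int b, int c) {
    Face f = {a, b, c, 0,0,0,0, true};
    face_plane(f, P);
    if (f.nx*ox + f.ny*oy + f.nz*oz - f.d > 0) {  // orient outward
      std::swap(f.b, f.c);
      face_plane(f, P);
    }
    faces.push_back(f);
  };
  add_face(i0, i1, i2); add_face(i0, i1, i3); add_face(i0, i2, i3); add_face(i1, i2, i3);

  std::vector<int> visible;
  for (int p = 0; p < n; ++p) {
    if (p == i0 || p == i1 || p == i2 || p == i3) continue;
    visible.clear();
    for (size_t f = 0; f < faces.size(); ++f) {
      if (!faces[f].alive) continue;
      if (faces[f].nx*P(p,0) + faces[f].ny*P(p,1) + faces[f].nz*P(p,2) - faces[f].d > eps)
        visible.push_back((int)f);
    }
    if (visible.empty()) continue;
    std::map<std::pair<int,int>, int> edge_count;
    for (int f : visible) {
      int v[3] = {faces[f].a, faces[f].b, faces[f].c};
      for (int e = 0; e < 3; ++e) {
        int a = v[e], b = v[(e+1)%3];
        edge_count[{std::min(a,b), std::max(a,b)}]++;
      }
      faces[f].alive = false;
    }
    for (const auto &ec : edge_count)
      if (ec.second == 1) add_face(ec.first.first, ec.first.second, p);
  }

  double vol = 0, area = 0, cx = 0, cy = 0, cz = 0;
  for (const auto &f : faces) {
    if (!f.alive) continue;
    double ax = P(f.a,0)-ox, ay = P(f.a,1)-oy, az = P(f.a,2)-oz;
    double bx = P(f.b,0)-ox, by = P(f.b,1)-oy, bz = P(f.b,2)-oz;
    double qx = P(f.c,0)-ox, qy = P(f.c,1)-oy, qz = P(f.c,2)-oz;
    double crx = by*qz - bz*qy, cry = bz*qx - bx*qz, crz = bx*qy - by*qx;
    double v6 = ax*crx + ay*cry + az*crz;            // 6 * signed tet volume
    vol += v6 / 6.0;
    cx += v6 / 6.0 * (ox + (ax + bx + qx) / 4.0);
    cy += v6 / 6.0 * (oy + (ay + by + qy) / 4.0);
    cz += v6 / 6.0 * (oz + (az + bz + qz) / 4.0);
    double ex1 = bx-ax, ey1 = by-ay, ez1 = bz-az;
    double ex2 = qx-ax, ey2 = qy-ay, ez2 = qz-az;
    double fx = ey1*ez2 - ez1*ey2, fy = ez1*ex2 - ex1*ez2, fz = ex1*ey2 - ey1*ex2;
    area += 0.5 * std::sqrt(fx*fx + fy*fy + fz*fz);
  }
  if (vol <= 0) return deg;
  NumericVector cen = NumericVector::create(cx/vol, cy/vol, cz/vol);
  return List::create(_["volume"] = vol, _["centroid"] = cen,
                      _["area"] = area, _["degenerate"] = false);
}

// --------------------------------------------------------- iso-surface area

// Marching-tetrahedra surface area of the level set {vol == level}, with
// voxel spacing (sx, sy, sz). Cube corners are bit-indexed (x=1, y=2, z=4)
// and split into 6 tetrahedra around the 0-7 diagonal.
// [[Rcpp::export]]
double cpp_mt_area(NumericVector vol, IntegerVector dim, NumericVector spacing, double level) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  static const int TET[6][4] = {
    {0,1,3,7},{0,3,2,7},{0,2,6,7},{0,6,4,7},{0,4,5,7},{0,5,1,7}};
  double area = 0.0;
  double cpos[8][3], val[8];
  for (int k = 0; k + 1 < nz; ++k)
    for (int j = 0; j + 1 < ny; ++j)
      for (int i = 0; i + 1 < nx; ++i) {
        bool any_hi = false, any_lo = false;
        for (int c = 0; c < 8; ++c) {
          int di = c & 1, dj = (c >> 1) & 1, dk = (c >> 2) & 1;
          val[c] = vol[idx3(i + di, j + dj, k + dk, nx, ny)];
          cpos[c][0] = (i + di) * sx; cpos[c][1] = (j + dj) * sy; cpos[c][2] = (k + dk) * sz;
          if (val[c] > level) any_hi = true; else any_lo = true;
        }
        if (!any_hi || !any_lo) continue;
        for (int t = 0; t < 6; ++t) {
          int id[4] = {TET[t][0], TET[t][1], TET[t][2], TET[t][3]};
          int above[4], na = 0, nb = 0, below[4];
          for (int c = 0; c < 4; ++c) {
            if (val[id[c]] > level) above[na++] = id[c]; else below[nb++] = id[c];
          }
          if (na == 0 || na == 4) continue;
          auto interp = [&](int hi, int lo, double *out) {
            double th = (level - val[lo]) / (val[hi] - val[lo]);
            for (int c = 0; c < 3; ++c)
              out[c] = cpos[lo][c] + th * (cpos[hi][c] - cpos[lo][c]);
          };
          auto tri_area = [&](double *p, double *q, double *r) {
            double ux = q[0]-p[0], uy = q[1]-p[1], uz = q[2]-p[2];
            double vx = r[0]-p[0], vy = r[1]-p[1], vz = r[2]-p[2];
            double cx = uy*vz - uz*vy, cy = uz*vx - ux*vz, cz = ux*vy - uy*vx;
            return 0.5 * std::sqrt(cx*cx + cy*cy + cz*cz);
          };
          double p1[3], p2[3], p3[3], p4[3];
          if (na == 1 || na == 3) {
            int apex = (na == 1) ? above[0] : below[0];
            int *others = (na == 1) ? below : above;
            if (na == 1) {
              interp(apex, others[0], p1); interp(apex, others[1], p2); interp(apex, others[2], p3);
            } else {
              interp(others[0], apex, p1); interp(others[1], apex, p2); interp(others[2], apex, p3);
            }
            area += tri_area(p1, p2, p3);
          } else {  // na == 2: quad A-C, A-D, B-D, B-C
            interp(above[0], below[0], p1);
            interp(above[0], below[1], p2);
            interp(above[1], below[1], p3);
            interp(above[1], below[0], p4);
            area += tri_area(p1, p2, p3) + tri_area(p1, p3, p4);
          }
        }
      }
  return area;
}

// Marching-tetrahedra mesh of the level set with welded vertices, smoothed
// by Taubin's shrink-compensating lambda/mu filter, then measured. Flat
// axis-aligned faces stay exact; staircase oscillation on oblique/curved
// surfaces is flattened out instead of being counted as extra area.
// [[Rcpp::export]]
double cpp_mt_area_taubin(NumericVector vol, IntegerVector dim,
                          NumericVector spacing, double level,
                          int iterations) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  static const int TET[6][4] = {
    {0,1,3,7},{0,3,2,7},{0,2,6,7},{0,6,4,7},{0,4,5,7},{0,5,1,7}};
  std::map<std::pair<long long,long long>, int> vid;
  std::vector<double> vx, vy, vz;
  std::vector<int> tri;

  long long corner_lin[8];
  double cpos[8][3], val[8];
  auto vertex_on = [&](int a, int b) {
    long long la = corner_lin[a], lb = corner_lin[b];
    if (la > lb) std::swap(la, lb);
    auto key = std::make_pair(la, lb);
    auto it = vid.find(key);
    if (it != vid.end()) return it->second;
    double th = (level - val[a]) / (val[b] - val[a]);
    int id = (int)vx.size();
    vx.push_back(cpos[a][0] + th * (cpos[b][0] - cpos[a][0]));
    vy.push_back(cpos[a][1] + th * (cpos[b][1] - cpos[a][1]));
    vz.push_back(cpos[a][2] + th * (cpos[b][2] - cpos[a][2]));
    vid[key] = id;
    return id;
  };

  for (int k = 0; k + 1 < nz; ++k)
    for (int j = 0; j + 1 < ny; ++j)
      for (int i = 0; i + 1 < nx; ++i) {
        bool any_hi = false, any_lo = false;
        for (int c = 0; c < 8; ++c) {
          int di = c & 1, dj = (c >> 1) & 1, dk = (c >> 2) & 1;
          corner_lin[c] = idx3(i + di, j + dj, k + dk, nx, ny);
          val[c] = vol[corner_lin[c]];
          cpos[c][0] = (i + di) * sx; cpos[c][1] = (j + dj) * sy;
          cpos[c][2] = (k + dk) * sz;
          if (val[c] > level) any_hi = true; else any_lo = true;
        }
        if (!any_hi || !any_lo) continue;
        for (int t = 0; t < 6; ++t) {
          int above[4], below[4], na = 0, nb = 0;
          for (int c = 0; c < 4; ++c) {
            int id = TET[t][c];
            if (val[id] > level) above[na++] = id; else below[nb++] = id;
          }
          if (na == 0 || na == 4) continue;
          if (na == 1 || na == 3) {
            int apex = (na == 1) ? above[0] : below[0];
            int *oth = (na == 1) ? below : above;
            int v1 = vertex_on(apex, oth[0]);
            int v2 = vertex_on(apex, oth[1]);
            int v3 = vertex_on(apex, oth[2]);
            tri.push_back(v1); tri.push_back(v2); tri.push_back(v3);
          } else {
            int v1 = vertex_on(above[0], below[0]);
            int v2 = vertex_on(above[0], below[1]);
            int v3 = vertex_on(above[1], below[1]);
            int v4 = vertex_on(above[1], below[0]);
            tri.push_back(v1); tri.push_back(v2); tri.push_back(v3);
            tri.push_back(v1); tri.push_back(v3); tri.push_back(v4);
          }
        }
      }

  int nv = (int)vx.size();
  // vertex adjacency for the umbrella operator
  std::vector<std::vector<int>> adj(nv);
  for (size_t s = 0; s < tri.size(); s += 3) {
    int a = tri[s], b = tri[s + 1], c = tri[s + 2];
    adj[a].push_back(b); adj[a].push_back(c);
    adj[b].push_back(a); adj[b].push_back(c);
    adj[c].push_back(a); adj[c].push_back(b);
  }
  for (int v = 0; v < nv; ++v) {
    std::sort(adj[v].begin(), adj[v].end());
    adj[v].erase(std::unique(adj[v].begin(), adj[v].end()), adj[v].end());
  }
  const double lambda = 0.5, mu = -0.53;
  std::vector<double> nx2(nv), ny2(nv), nz2(nv);
  for (int it = 0; it < iterations; ++it) {
    for (int pass = 0; pass < 2; ++pass) {
      double f = pass == 0 ? lambda : mu;
      for (int v = 0; v < nv; ++v) {
        if (adj[v].empty()) { nx2[v] = vx[v]; ny2[v] = vy[v]; nz2[v] = vz[v]; continue; }
        double mx = 0, my = 0, mz = 0;
        for (int w : adj[v]) { mx += vx[w]; my += vy[w]; mz += vz[w]; }
        double nn = (double)adj[v].size();
        nx2[v] = vx[v] + f * (mx / nn - vx[v]);
        ny2[v] = vy[v] + f * (my / nn - vy[v]);
        nz2[v] = vz[v] + f * (mz / nn - vz[v]);
      }
      vx.swap(nx2); vy.swap(ny2); vz.swap(nz2);
    }
  }

  double area = 0;
  for (size_t s = 0; s < tri.size(); s += 3) {
    int a = tri[s], b = tri[s + 1], c = tri[s + 2];
    double ux = vx[b]-vx[a], uy = vy[b]-vy[a], uz = vz[b]-vz[a];
    double wx = vx[c]-vx[a], wy = vy[c]-vy[a], wz = vz[c]-vz[a];
    double crx = uy*wz - uz*wy, cry = uz*wx - ux*wz, crz = ux*wy - uy*wx;
    area += 0.5 * std::sqrt(crx*crx + cry*cry + crz*crz);
  }
  return area;
}

// ------------------------------------------------------------ Gaussian blur

// Separable Gaussian with per-axis sigma (voxel units); replicate boundary.
// [[Rcpp::export]]
NumericVector cpp_gauss3d(NumericVector vol, IntegerVector dim, NumericVector sigma) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  long long n = (long long)nx * ny * nz;
  std::vector<double> a(vol.begin(), vol.end()), b(n);
  int nd[3] = {nx, ny, nz};
  long long stride[3] = {1, nx, (long long)nx * ny};
  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma[ax];
    if (s <= 0) continue;
    int r = std::max(1, (int)std::ceil(3.0 * s));
    std::vector<double> w(2 * r + 1);
    double tot = 0;
    for (int t = -r; t <= r; ++t) { w[t + r] = std::exp(-0.5 * t * t / (s * s)); tot += w[t + r]; }
    for (auto &x : w) x /= tot;
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          int pos[3] = {i, j, k};
          long long base = idx3(i, j, k, nx, ny);
          double acc = 0;
          for (int t = -r; t <= r; ++t) {
            int q = pos[ax] + t;
            if (q < 0) q = 0;
            if (q >= nd[ax]) q = nd[ax] - 1;
            acc += w[t + r] * a[base + (long long)(q - pos[ax]) * stride[ax]];
          }
          b[base] = acc;
        }
    std::swap(a, b);
  }
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dim;
  return out;
}

// ------------------------------------------------------------- voxelization

// Rasterize a union of capsules (x0,y0,z0,x1,y1,z1,r; µm) and ellipsoids
// (cx,cy,cz,a,b,c; µm) onto a voxel grid. Voxel (i,j,k), 0-based, has its
// centre at ((i+0.5)*sx, (j+0.5)*sy, (k+0.5)*sz) µm.
// [[Rcpp::export]]
LogicalVector cpp_rasterize(IntegerVector dim, NumericVector spacing,
                            NumericMatrix capsules, NumericMatrix ellipsoids) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  long long n = (long long)nx * ny * nz;
  LogicalVector mask(n, false);

  auto vrange = [&](double lo, double hi, double s, int nmax, int &v0, int &v1) {
    v0 = std::max(0, (int)std::floor(lo / s - 0.5));
    v1 = std::min(nmax - 1, (int)std::ceil(hi / s - 0.5));
  };

  for (int e = 0; e < ellipsoids.nrow(); ++e) {
    double cx = ellipsoids(e,0), cy = ellipsoids(e,1), cz = ellipsoids(e,2);
    double ea = ellipsoids(e,3), eb = ellipsoids(e,4), ec = ellipsoids(e,5);
    int i0,i1,j0,j1,k0,k1;
    vrange(cx-ea, cx+ea, sx, nx, i0, i1);
    vrange(cy-eb, cy+eb, sy, ny, j0, j1);
    vrange(cz-ec, cz+ec, sz, nz, k0, k1);
    for (int k = k0; k <= k1; ++k)
      for (int j = j0; j <= j1; ++j)
        for (int i = i0; i <= i1; ++i) {
          double px = (i+0.5)*sx, py = (j+0.5)*sy, pz = (k+0.5)*sz;
          double q = (px-cx)*(px-cx)/(ea*ea) + (py-cy)*(py-cy)/(eb*eb) + (pz-cz)*(pz-cz)/(ec*ec);
          if (q <= 1.0) mask[idx3(i,j,k,nx,ny)] = true;
        }
  }
  for (int s = 0; s < capsules.nrow(); ++s) {
    double x0 = capsules(s,0), y0 = capsules(s,1), z0 = capsules(s,2);
    double x1 = capsules(s,3), y1 = capsules(s,4), z1 = capsules(s,5);
    double r = capsules(s,6);
    double ux = x1-x0, uy = y1-y0, uz = z1-z0;
    double L2 = ux*ux + uy*uy + uz*uz;
    int i0,i1,j0,j1,k0,k1;
    vrange(std::min(x0,x1)-r, std::max(x0,x1)+r, sx, nx, i0, i1);
    vrange(std::min(y0,y1)-r, std::max(y0,y1)+r, sy, ny, j0, j1);
    vrange(std::min(z0,z1)-r, std::max(z0,z1)+r, sz, nz, k0, k1);
    for (int k = k0; k <= k1; ++k)
      for (int j = j0; j <= j1; ++j)
        for (int i = i0; i <= i1; ++i) {
          double px = (i+0.5)*sx, py = (j+0.5)*sy, pz = (k+0.5)*sz;
          double t = 0;
          if (L2 > 0) {
            t = ((px-x0)*ux + (py-y0)*uy + (pz-z0)*uz) / L2;
            if (t < 0) t = 0; else if (t > 1) t = 1;
          }
          double dx = px - (x0 + t*ux), dy = py - (y0 + t*uy), dz = pz - (z0 + t*uz);
          if (dx*dx + dy*dy + dz*dz <= r*r) mask[idx3(i,j,k,nx,ny)] = true;
        }
  }
  mask.attr("dim") = dim;
  return mask;
}

// Strict point-in-union test against a set of ellipsoids (cx,cy,cz,a,b,c)
// and capsules (x0..z1,r); used by the Monte-Carlo union integrals.
// [[Rcpp::export]]
LogicalVector cpp_inside_any(NumericMatrix pts, NumericMatrix ellipsoids,
                             NumericMatrix capsules) {
  int n = pts.nrow();
  LogicalVector out(n, false);
  const double tol = 1.0 - 1e-12;
  for (int q = 0; q < n; ++q) {
    double px = pts(q,0), py = pts(q,1), pz = pts(q,2);
    bool in = false;
    for (int e = 0; e < ellipsoids.nrow() && !in; ++e) {
      double dx = (px - ellipsoids(e,0)) / ellipsoids(e,3);
      double dy = (py - ellipsoids(e,1)) / ellipsoids(e,4);
      double dz = (pz - ellipsoids(e,2)) / ellipsoids(e,5);
      if (dx*dx + dy*dy + dz*dz < tol) in = true;
    }
    for (int s = 0; s < capsules.nrow() && !in; ++s) {
      double x0 = capsules(s,0), y0 = capsules(s,1), z0 = capsules(s,2);
      double ux = capsules(s,3)-x0, uy = capsules(s,4)-y0, uz = capsules(s,5)-z0;
      double r = capsules(s,6);
      double L2 = ux*ux + uy*uy + uz*uz;
      double t = 0;
      if (L2 > 0) {
        t = ((px-x0)*ux + (py-y0)*uy + (pz-z0)*uz) / L2;
        if (t < 0) t = 0; else if (t > 1) t = 1;
      }
      double dx = px-(x0+t*ux), dy = py-(y0+t*uy), dz = pz-(z0+t*uz);
      if (dx*dx + dy*dy + dz*dz < r*r*tol) in = true;
    }
    out[q] = in;
  }
  return out;
}

// Minimum distance from point p to the capsule axis segments (used by the
// generator to keep non-adjacent branches from fusing).
// [[Rcpp::export]]
NumericVector cpp_seg_dist(NumericMatrix segs, NumericVector p) {
  int n = segs.nrow();
  NumericVector out(n);
  for (int s = 0; s < n; ++s) {
    double x0 = segs(s,0), y0 = segs(s,1), z0 = segs(s,2);
    double ux = segs(s,3)-x0, uy = segs(s,4)-y0, uz = segs(s,5)-z0;
    double L2 = ux*ux + uy*uy + uz*uz;
    double t = 0;
    if (L2 > 0) {
      t = ((p[0]-x0)*ux + (p[1]-y0)*uy + (p[2]-z0)*uz) / L2;
      if (t < 0) t = 0; else if (t > 1) t = 1;
    }
    double dx = p[0]-(x0+t*ux), dy = p[1]-(y0+t*uy), dz = p[2]-(z0+t*uz);
    out[s] = std::sqrt(dx*dx + dy*dy + dz*dz);
  }
  return out;
}
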