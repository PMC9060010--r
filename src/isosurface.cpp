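#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Isosurface area by marching tetrahedra: each grid cube is split into six
// tetrahedra sharing the main diagonal; within a tetrahedron the level
// surface is one or two triangles whose vertices are linear interpolations
// along crossed edges. For a binary field the caller smooths first (the area
// of the raw-binary surface is badly biased).

namespace {

struct P3 { double x, y, z; };

inline P3 lerp(const P3 &a, const P3 &b, double va, double vb, double level) {
  double t = (level - va) / (vb - va);
  return {a.x + t * (b.x - a.x), a.y + t * (b.y - a.y), a.z + t * (b.z - a.z)};
}

inline double triArea(const P3 &a, const P3 &b, const P3 &c) {
  double ux = b.x - a.x, uy = b.y - a.y, uz = b.z - a.z;
  double vx = c.x - a.x, vy = c.y - a.y, vz = c.z - a.z;
  double cx = uy * vz - uz * vy, cy = uz * vx - ux * vz, cz = ux * vy - uy * vx;
  return 0.5 * std::sqrt(cx * cx + cy * cy + cz * cz);
}

double tetArea(const P3 p[4], const double v[4], double level) {
  bool in[4];
  int nin = 0;
  for (int i = 0; i < 4; ++i) {
    in[i] = v[i] > level;
    if (in[i]) ++nin;
  }
  if (nin == 0 || nin == 4) return 0.0;
  if (nin == 1 || nin == 3) {
    // one odd vertex: triangle on the three edges from it
    bool want = (nin == 1);
    int odd = 0;
    for (int i = 0; i < 4; ++i)
      if (in[i] == want) odd = i;
    P3 q[3];
    int k = 0;
    for (int i = 0; i < 4; ++i)
      if (i != odd) q[k++] = lerp(p[odd], p[i], v[odd], v[i], level);
    return triArea(q[0], q[1], q[2]);
  }
  // 2-2 split: quad over the four crossed edges
  int a = -1, b = -1, cc = -1, d = -1;
  for (int i = 0; i < 4; ++i) {
    if (in[i]) { if (a < 0) a = i; else b = i; }
    else       { if (cc < 0) cc = i; else d = i; }
  }
  P3 pac = lerp(p[a], p[cc], v[a], v[cc], level);
  P3 pad = lerp(p[a], p[d], v[a], v[d], level);
  P3 pbd = lerp(p[b], p[d], v[b], v[d], level);
  P3 pbc = lerp(p[b], p[cc], v[b], v[cc], level);
  return triArea(pac, pad, pbd) + triArea(pac, pbd, pbc);
}

} // namespace

// vol is an (nz, ny, nx) field; spacing = (dz, dy, dx) um. Returns the total
// area (um^2) of the `level` isosurface.
// [[Rcpp::export]]
double cpp_isosurface_area(NumericVector vol, IntegerVector dim,
                           NumericVector spacing, double level) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const double dz = spacing[0], dy = spacing[1], dx = spacing[2];
  // cube corner offsets (z, y, x), corner id bit order: 1 = z, 2 = y, 4 = x
  // six tetrahedra sharing diagonal corner0 (0,0,0) -> corner7 (1,1,1)
  static const int tets[6][4] = {{0, 1, 3, 7}, {0, 3, 2, 7}, {0, 2, 6, 7},
                                 {0, 6, 4, 7}, {0, 4, 5, 7}, {0, 5, 1, 7}};
  double total = 0.0;
  for (int x = 0; x + 1 < nx; ++x)
    for (int y = 0; y + 1 < ny; ++y)
      for (int z = 0; z + 1 < nz; ++z) {
        double v[8];
        P3 p[8];
        bool any = false, all = true;
        for (int c = 0; c < 8; ++c) {
          int zz = z + ((c & 1) ? 1 : 0);
          int yy = y + ((c & 2) ? 1 : 0);
          int xx = x + ((c & 4) ? 1 : 0);
          v[c] = vol[zz + nz * (yy + ny * xx)];
          p[c] = {xx * dx, yy * dy, zz * dz};
          if (v[c] > level) any = true; else all = false;
        }
        if (!any || all) continue;
        for (int t = 0; t < 6; ++t) {
          P3 tp[4];
          double tv[4];
          for (int i = 0; i < 4; ++i) {
            tp[i] = p[tets[t][i]];
            tv[i] = v[tets[t][i]];
          }
          total += tetArea(tp, tv, level);
        }
      }
  return total;
}
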