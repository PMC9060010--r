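#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Topology-preserving 3D thinning to a curve skeleton.
//
// A voxel is "simple" (deletable without changing topology) when, in its
// 3x3x3 neighbourhood, (a) the foreground voxels of the 26-neighbourhood form
// exactly one 26-connected component and (b) the background voxels of the
// 18-neighbourhood form exactly one 6-connected component that touches a
// 6-neighbour of the centre (Bertrand & Malandain characterization).
// Curve endpoints (exactly one foreground 26-neighbour) and isolated voxels
// are preserved. Deletion is distance-ordered (Pudney-style), one chamfer
// distance level at a time: the object erodes uniformly from its boundary,
// so the surviving curve follows the distance ridge and stays centred, and
// fibre ends retract by at most one layer per level rather than cascading.
// Only simple points are ever removed, which guarantees homotopy.

namespace {

struct Cube {
  bool fg[27]; // (dz+1) + 3*(dy+1) + 9*(dx+1); index 13 is the centre
};

inline int cidx(int dz, int dy, int dx) {
  return (dz + 1) + 3 * (dy + 1) + 9 * (dx + 1);
}

// number of 26-components of the foreground within the 26-neighbourhood
int fg26_components(const Cube &c) {
  int lab[27];
  for (int i = 0; i < 27; ++i) lab[i] = 0;
  int ncomp = 0;
  for (int i = 0; i < 27; ++i) {
    if (i == 13 || !c.fg[i] || lab[i]) continue;
    ++ncomp;
    int stack[27], top = 0;
    stack[top++] = i;
    lab[i] = ncomp;
    while (top) {
      int cur = stack[--top];
      int z = cur % 3, y = (cur / 3) % 3, x = cur / 9;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            int zz = z + dz, yy = y + dy, xx = x + dx;
            if (zz < 0 || zz > 2 || yy < 0 || yy > 2 || xx < 0 || xx > 2)
              continue;
            int j = zz + 3 * yy + 9 * xx;
            if (j == 13 || j == cur || !c.fg[j] || lab[j]) continue;
            lab[j] = ncomp;
            stack[top++] = j;
          }
    }
  }
  return ncomp;
}

// number of 6-components of the background within the 18-neighbourhood that
// are 6-adjacent to the centre
int bg6_components(const Cube &c) {
  bool in18[27];
  for (int i = 0; i < 27; ++i) {
    int z = i % 3 - 1, y = (i / 3) % 3 - 1, x = i / 9 - 1;
    in18[i] = (std::abs(z) + std::abs(y) + std::abs(x)) <= 2 && i != 13;
  }
  int lab[27];
  for (int i = 0; i < 27; ++i) lab[i] = 0;
  int ncomp = 0;
  static const int d6[6][3] = {{-1, 0, 0}, {1, 0, 0}, {0, -1, 0},
                               {0, 1, 0},  {0, 0, -1}, {0, 0, 1}};
  for (int s = 0; s < 6; ++s) {
    int i = cidx(d6[s][0], d6[s][1], d6[s][2]);
    if (c.fg[i] || lab[i]) continue; // must be background 6-neighbour, unseen
    ++ncomp;
    int stack[27], top = 0;
    stack[top++] = i;
    lab[i] = ncomp;
    while (top) {
      int cur = stack[--top];
      int z = cur % 3 - 1, y = (cur / 3) % 3 - 1, x = cur / 9 - 1;
      for (int t = 0; t < 6; ++t) {
        int zz = z + d6[t][0], yy = y + d6[t][1], xx = x + d6[t][2];
        if (zz < -1 || zz > 1 || yy < -1 || yy > 1 || xx < -1 || xx > 1)
          continue;
        int j = cidx(zz, yy, xx);
        if (j == 13 || !in18[j] || c.fg[j] || lab[j]) continue;
        lab[j] = ncomp;
        stack[top++] = j;
      }
    }
  }
  return ncomp;
}

// Interior point of a one-voxel-thick plate: exactly two background
// 6-neighbours and they are an opposite pair. Deleting such a voxel pierces
// an in-plane hole (legal for 3D homotopy, since the hole is open above and
// below, but it shreds ribbons into locked "ladders"); protecting it forces
// ribbons to erode from their edges and collapse to clean curves.
bool plate_interior(const Cube &c) {
  static const int pairs[3][2][3] = {{{-1, 0, 0}, {1, 0, 0}},
                                     {{0, -1, 0}, {0, 1, 0}},
                                     {{0, 0, -1}, {0, 0, 1}}};
  int nbg = 0;
  int bgAxis[3] = {0, 0, 0};
  for (int ax = 0; ax < 3; ++ax)
    for (int s = 0; s < 2; ++s)
      if (!c.fg[cidx(pairs[ax][s][0], pairs[ax][s][1], pairs[ax][s][2])]) {
        ++nbg;
        ++bgAxis[ax];
      }
  return nbg == 2 && (bgAxis[0] == 2 || bgAxis[1] == 2 || bgAxis[2] == 2);
}

} // namespace

// [[Rcpp::export]]
LogicalVector cpp_thin3d(LogicalVector mask, IntegerVector dim) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const int N = nz * ny * nx;
  LogicalVector img = clone(mask);

  auto getCube = [&](int cz, int cy, int cx, Cube &c) {
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          int z = cz + dz, y = cy + dy, x = cx + dx;
          bool v = false;
          if (z >= 0 && z < nz && y >= 0 && y < ny && x >= 0 && x < nx)
            v = img[z + nz * (y + ny * x)];
          c.fg[cidx(dz, dy, dx)] = v;
        }
  };

  auto nFgNeighbors = [&](const Cube &c) {
    int n = 0;
    for (int i = 0; i < 27; ++i)
      if (i != 13 && c.fg[i]) ++n;
    return n;
  };

  auto deletable = [&](int i) {
    int cz = i % nz, cy = (i / nz) % ny, cx = i / (nz * ny);
    Cube c;
    getCube(cz, cy, cx, c);
    if (nFgNeighbors(c) <= 1) return false; // endpoint/isolated: preserve
    if (plate_interior(c)) return false;
    return fg26_components(c) == 1 && bg6_components(c) == 1;
  };

  // chamfer (3-4-5) distance to background: cheap, and only the erosion
  // ORDER matters here, not metric exactness
  std::vector<int> dist(N, 0);
  const int BIG = 1 << 28;
  for (int i = 0; i < N; ++i) dist[i] = img[i] ? BIG : 0;
  auto relax = [&](int i, int z, int y, int x, int dz, int dy, int dx) {
    int m = std::abs(dz) + std::abs(dy) + std::abs(dx);
    int w = (m == 1) ? 3 : (m == 2 ? 4 : 5);
    int zz = z + dz, yy = y + dy, xx = x + dx;
    if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) {
      if (w < dist[i]) dist[i] = w; // outside the grid counts as background
      return;
    }
    int j = zz + nz * (yy + ny * xx);
    if (dist[j] + w < dist[i]) dist[i] = dist[j] + w;
  };
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        int i = z + nz * (y + ny * x);
        if (!img[i]) continue;
        for (int dx = -1; dx <= 0; ++dx)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dz = -1; dz <= 1; ++dz) {
              if (dx == 0 && (dy > 0 || (dy == 0 && dz >= 0))) continue;
              relax(i, z, y, x, dz, dy, dx);
            }
      }
  for (int x = nx - 1; x >= 0; --x)
    for (int y = ny - 1; y >= 0; --y)
      for (int z = nz - 1; z >= 0; --z) {
        int i = z + nz * (y + ny * x);
        if (!img[i]) continue;
        for (int dx = 0; dx <= 1; ++dx)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dz = -1; dz <= 1; ++dz) {
              if (dx == 0 && (dy < 0 || (dy == 0 && dz <= 0))) continue;
              relax(i, z, y, x, dz, dy, dx);
            }
      }

  std::vector<int> order;
  order.reserve(N);
  for (int i = 0; i < N; ++i)
    if (img[i]) order.push_back(i);
  std::stable_sort(order.begin(), order.end(),
                   [&](int a, int b) { return dist[a] < dist[b]; });

  // one distance level at a time: within a level only voxels whose initial
  // distance equals the level are candidates, so tube ends retract by at
  // most one layer per level instead of cascading arbitrarily deep
  size_t lo = 0;
  while (lo < order.size()) {
    int level = dist[order[lo]];
    size_t hi = lo;
    while (hi < order.size() && dist[order[hi]] == level) ++hi;
    bool changed = true;
    while (changed) {
      changed = false;
      for (size_t k = lo; k < hi; ++k)
        if (img[order[k]] && deletable(order[k])) {
          img[order[k]] = false;
          changed = true;
        }
    }
    lo = hi;
  }

  // final cleanup over everything that remains: by now fibres are one-voxel
  // curves whose interior points are non-simple and whose ends are protected
  // endpoints, so only redundant staircase leftovers can be removed
  bool changed = true;
  while (changed) {
    changed = false;
    for (int i : order)
      if (img[i] && deletable(i)) {
        img[i] = false;
        changed = true;
      }
  }
  return img;
}
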