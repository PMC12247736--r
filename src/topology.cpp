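// 3D digital-topology primitives shared by thinning, classification and
// graph decomposition: 26/6-connected component labeling, 26-neighbor
// counts, and the Bertrand-Malandain simple-point test used by the
// 6-subiteration medial-axis thinning.
#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cstdint>

using namespace Rcpp;

namespace {

struct Grid {
  int nx, ny, nz;
  inline std::size_t idx(int x, int y, int z) const {
    return static_cast<std::size_t>(x) +
           static_cast<std::size_t>(nx) * (static_cast<std::size_t>(y) +
           static_cast<std::size_t>(ny) * static_cast<std::size_t>(z));
  }
  inline bool inside(int x, int y, int z) const {
    return x >= 0 && x < nx && y >= 0 && y < ny && z >= 0 && z < nz;
  }
};

// 26-neighborhood offsets (excludes center)
static const int OFF26[26][3] = {
  {-1,-1,-1},{0,-1,-1},{1,-1,-1},{-1,0,-1},{0,0,-1},{1,0,-1},
  {-1,1,-1},{0,1,-1},{1,1,-1},
  {-1,-1,0},{0,-1,0},{1,-1,0},{-1,0,0},{1,0,0},
  {-1,1,0},{0,1,0},{1,1,0},
  {-1,-1,1},{0,-1,1},{1,-1,1},{-1,0,1},{0,0,1},{1,0,1},
  {-1,1,1},{0,1,1},{1,1,1}
};

static const int OFF6[6][3] = {
  {1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}
};

Grid grid_of(const IntegerVector& dims) {
  Grid g;
  g.nx = dims[0]; g.ny = dims[1]; g.nz = dims[2];
  return g;
}

// --- simple-point test -------------------------------------------------
// A foreground voxel p is simple iff
//   T26(p) = number of 26-components of foreground in N26(p) == 1, and
//   T6(p)  = number of 6-components of background in N18(p) that are
//            6-adjacent to p == 1.
// Deleting a simple point preserves both foreground 26-topology and
// background 6-topology (Bertrand & Malandain characterization; the
// topology-preservation contract of Lee-style thinning).

// neighborhood is a 27-long array in (dx+1) + 3*(dy+1) + 9*(dz+1) order,
// nb[13] is the center (ignored).
inline int nbindex(int dx, int dy, int dz) {
  return (dx + 1) + 3 * (dy + 1) + 9 * (dz + 1);
}

bool is_simple_point(const uint8_t* nb) {
  // T26: 26-components of foreground among the 26 neighbors
  int labels[27];
  for (int i = 0; i < 27; ++i) labels[i] = 0;
  int ncomp_fg = 0;
  for (int i = 0; i < 27; ++i) {
    if (i == 13 || !nb[i] || labels[i]) continue;
    ++ncomp_fg;
    if (ncomp_fg > 1) return false;
    // BFS over fg neighbors, 26-adjacency within the 3x3x3 box
    std::queue<int> q;
    q.push(i); labels[i] = ncomp_fg;
    while (!q.empty()) {
      int c = q.front(); q.pop();
      int cx = c % 3 - 1, cy = (c / 3) % 3 - 1, cz = c / 9 - 1;
      for (int k = 0; k < 26; ++k) {
        int x = cx + OFF26[k][0], y = cy + OFF26[k][1], z = cz + OFF26[k][2];
        if (x < -1 || x > 1 || y < -1 || y > 1 || z < -1 || z > 1) continue;
        int j = nbindex(x, y, z);
        if (j == 13 || !nb[j] || labels[j]) continue;
        labels[j] = ncomp_fg;
        q.push(j);
      }
    }
  }
  if (ncomp_fg != 1) return false;

  // T6: 6-components of background within N18 that touch a 6-neighbor of p
  bool in18[27];
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int a = std::abs(dx) + std::abs(dy) + std::abs(dz);
        in18[nbindex(dx, dy, dz)] = (a == 1 || a == 2);
      }
  int blabels[27];
  for (int i = 0; i < 27; ++i) blabels[i] = 0;
  int ncomp_bg = 0;
  for (int s = 0; s < 6; ++s) {
    int i = nbindex(OFF6[s][0], OFF6[s][1], OFF6[s][2]);
    if (nb[i] || blabels[i]) continue;
    ++ncomp_bg;
    if (ncomp_bg > 1) return false;
    std::queue<int> q;
    q.push(i); blabels[i] = ncomp_bg;
    while (!q.empty()) {
      int c = q.front(); q.pop();
      int cx = c % 3 - 1, cy = (c / 3) % 3 - 1, cz = c / 9 - 1;
      for (int k = 0; k < 6; ++k) {
        int x = cx + OFF6[k][0], y = cy + OFF6[k][1], z = cz + OFF6[k][2];
        if (x < -1 || x > 1 || y < -1 || y > 1 || z < -1 || z > 1) continue;
        int j = nbindex(x, y, z);
        if (!in18[j] || nb[j] || blabels[j]) continue;
        blabels[j] = ncomp_bg;
        q.push(j);
      }
    }
  }
  return ncomp_bg == 1;
}

inline void fill_neighborhood(const std::vector<uint8_t>& img, const Grid& g,
                              int x, int y, int z, uint8_t* nb) {
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int xx = x + dx, yy = y + dy, zz = z + dz;
        nb[nbindex(dx, dy, dz)] =
          g.inside(xx, yy, zz) ? img[g.idx(xx, yy, zz)] : 0;
      }
}

inline int count_nb26(const std::vector<uint8_t>& img, const Grid& g,
                      int x, int y, int z) {
  int n = 0;
  for (int k = 0; k < 26; ++k) {
    int xx = x + OFF26[k][0], yy = y + OFF26[k][1], zz = z + OFF26[k][2];
    if (g.inside(xx, yy, zz) && img[g.idx(xx, yy, zz)]) ++n;
  }
  return n;
}

} // namespace

// [[Rcpp::export(name = ".cpp_thin3d")]]
LogicalVector cpp_thin3d(LogicalVector mask, IntegerVector dims) {
  Grid g = grid_of(dims);
  std::size_t n = static_cast<std::size_t>(g.nx) * g.ny * g.nz;
  std::vector<uint8_t> img(n);
  for (std::size_t i = 0; i < n; ++i) img[i] = mask[i] ? 1 : 0;

  // active voxel list to avoid full-grid sweeps
  std::vector<std::size_t> fg;
  fg.reserve(1024);
  for (int z = 0; z < g.nz; ++z)
    for (int y = 0; y < g.ny; ++y)
      for (int x = 0; x < g.nx; ++x)
        if (img[g.idx(x, y, z)]) fg.push_back(g.idx(x, y, z));

  // 6 border directions: a voxel is a border of direction d when its
  // d-neighbor is background. Order U,D,N,S,E,W as in Lee et al.
  const int DIRS[6][3] = {
    {0,0,-1},{0,0,1},{0,-1,0},{0,1,0},{-1,0,0},{1,0,0}
  };

  uint8_t nb[27];
  bool changed = true;
  std::vector<std::size_t> cand;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      cand.clear();
      for (std::size_t i : fg) {
        if (!img[i]) continue;
        int x = static_cast<int>(i % g.nx);
        int y = static_cast<int>((i / g.nx) % g.ny);
        int z = static_cast<int>(i / (static_cast<std::size_t>(g.nx) * g.ny));
        int bx = x + DIRS[d][0], by = y + DIRS[d][1], bz = z + DIRS[d][2];
        bool border = !g.inside(bx, by, bz) || !img[g.idx(bx, by, bz)];
        if (!border) continue;
        if (count_nb26(img, g, x, y, z) < 2) continue; // keep line endpoints
        fill_neighborhood(img, g, x, y, z, nb);
        if (is_simple_point(nb)) cand.push_back(i);
      }
      // sequential re-check: deletions earlier in the pass may invalidate
      // simplicity of later candidates
      for (std::size_t i : cand) {
        int x = static_cast<int>(i % g.nx);
        int y = static_cast<int>((i / g.nx) % g.ny);
        int z = static_cast<int>(i / (static_cast<std::size_t>(g.nx) * g.ny));
        fill_neighborhood(img, g, x, y, z, nb);
        if (is_simple_point(nb)) {
          img[i] = 0;
          changed = true;
        }
      }
    }
    if (changed) {
      // compact the active list
      std::vector<std::size_t> keep;
      keep.reserve(fg.size());
      for (std::size_t i : fg) if (img[i]) keep.push_back(i);
      fg.swap(keep);
    }
  }

  LogicalVector out(n);
  for (std::size_t i = 0; i < n; ++i) out[i] = img[i] != 0;
  out.attr("dim") = dims;
  return out;
}

// [[Rcpp::export(name = ".cpp_neighbor_count26")]]
IntegerVector cpp_neighbor_count26(LogicalVector mask, IntegerVector dims) {
  Grid g = grid_of(dims);
  std::size_t n = static_cast<std::size_t>(g.nx) * g.ny * g.nz;
  std::vector<uint8_t> img(n);
  for (std::size_t i = 0; i < n; ++i) img[i] = mask[i] ? 1 : 0;
  IntegerVector out(n);
  for (int z = 0; z < g.nz; ++z)
    for (int y = 0; y < g.ny; ++y)
      for (int x = 0; x < g.nx; ++x) {
        std::size_t i = g.idx(x, y, z);
        out[i] = img[i] ? count_nb26(img, g, x, y, z) : 0;
      }
  out.attr("dim") = dims;
  return out;
}

// [[Rcpp::export(name = ".cpp_label_components")]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  Grid g = grid_of(dims);
  std::size_t n = static_cast<std::size_t>(g.nx) * g.ny * g.nz;
  std::vector<uint8_t> img(n);
  for (std::size_t i = 0; i < n; ++i) img[i] = mask[i] ? 1 : 0;
  IntegerVector lab(n);
  int next = 0;
  std::vector<std::size_t> stack;
  const int (*offs)[3] = (connectivity == 6) ? OFF6 : OFF26;
  int noffs = (connectivity == 6) ? 6 : 26;
  for (std::size_t start = 0; start < n; ++start) {
    if (!img[start] || lab[start]) continue;
    ++next;
    stack.clear();
    stack.push_back(start);
    lab[start] = next;
    while (!stack.empty()) {
      std::size_t c = stack.back(); stack.pop_back();
      int x = static_cast<int>(c % g.nx);
      int y = static_cast<int>((c / g.nx) % g.ny);
      int z = static_cast<int>(c / (static_cast<std::size_t>(g.nx) * g.ny));
      for (int k = 0; k < noffs; ++k) {
        int xx = x + offs[k][0], yy = y + offs[k][1], zz = z + offs[k][2];
        if (!g.inside(xx, yy, zz)) continue;
        std::size_t j = g.idx(xx, yy, zz);
        if (img[j] && !lab[j]) {
          lab[j] = next;
          stack.push_back(j);
        }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}
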