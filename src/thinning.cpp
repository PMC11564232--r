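#include <Rcpp.h>
#include <vector>
#include <queue>
#include <array>
#include <cstdlib>
using namespace Rcpp;

// 3D binary volume utilities for (26,6) digital topology: foreground uses
// 26-adjacency, background 6-adjacency.  Volumes arrive as LogicalVector with
// a dim attribute (column-major, as R stores arrays).

static inline int vidx(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

static inline bool inside(int x, int y, int z, int nx, int ny, int nz) {
  return x >= 0 && y >= 0 && z >= 0 && x < nx && y < ny && z < nz;
}

// Extract the 3x3x3 neighbourhood of (x,y,z) into nb[27]; out-of-volume
// treated as background.  nb index = (dx+1) + 3*(dy+1) + 9*(dz+1).
static void neighbourhood(const std::vector<char> &vol, int x, int y, int z,
                          int nx, int ny, int nz, bool nb[27]) {
  int k = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx, ++k) {
        int xx = x + dx, yy = y + dy, zz = z + dz;
        nb[k] = inside(xx, yy, zz, nx, ny, nz) && vol[vidx(xx, yy, zz, nx, ny)];
      }
}

static inline int nb_index(int dx, int dy, int dz) {
  return (dx + 1) + 3 * (dy + 1) + 9 * (dz + 1);
}

// Number of 26-connected components among the 26 foreground neighbours
// (centre excluded).
static int fg_components26(const bool nb[27]) {
  bool seen[27] = {false};
  int ncomp = 0;
  for (int i = 0; i < 27; ++i) {
    if (i == 13 || !nb[i] || seen[i]) continue;
    ++ncomp;
    std::queue<int> q;
    q.push(i);
    seen[i] = true;
    while (!q.empty()) {
      int c = q.front(); q.pop();
      int cx = c % 3, cy = (c / 3) % 3, cz = c / 9;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            int xx = cx + dx, yy = cy + dy, zz = cz + dz;
            if (xx < 0 || yy < 0 || zz < 0 || xx > 2 || yy > 2 || zz > 2) continue;
            int j = xx + 3 * yy + 9 * zz;
            if (j == 13 || j == c || !nb[j] || seen[j]) continue;
            seen[j] = true;
            q.push(j);
          }
    }
  }
  return ncomp;
}

// Number of 6-connected components of background within the 18-neighbourhood
// that contain at least one face neighbour of the centre (the standard
// background condition for a (26,6) simple point).
static int bg_components6(const bool nb[27]) {
  // 18-neighbourhood: |dx|+|dy|+|dz| <= 2, excluding centre
  bool in18[27];
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int i = nb_index(dx, dy, dz);
        int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        in18[i] = (m >= 1 && m <= 2);
      }
  const int faces[6] = {nb_index(-1, 0, 0), nb_index(1, 0, 0),
                        nb_index(0, -1, 0), nb_index(0, 1, 0),
                        nb_index(0, 0, -1), nb_index(0, 0, 1)};
  bool seen[27] = {false};
  int ncomp = 0;
  for (int f = 0; f < 6; ++f) {
    int s = faces[f];
    if (nb[s] || seen[s]) continue;  // foreground face or already visited
    ++ncomp;
    std::queue<int> q;
    q.push(s);
    seen[s] = true;
    while (!q.empty()) {
      int c = q.front(); q.pop();
      int cx = c % 3 - 1, cy = (c / 3) % 3 - 1, cz = c / 9 - 1;
      const int d6[6][3] = {{-1,0,0},{1,0,0},{0,-1,0},{0,1,0},{0,0,-1},{0,0,1}};
      for (int k = 0; k < 6; ++k) {
        int xx = cx + d6[k][0], yy = cy + d6[k][1], zz = cz + d6[k][2];
        if (xx < -1 || yy < -1 || zz < -1 || xx > 1 || yy > 1 || zz > 1) continue;
        int j = nb_index(xx, yy, zz);
        if (!in18[j] || nb[j] || seen[j]) continue;
        seen[j] = true;
        q.push(j);
      }
    }
  }
  return ncomp;
}

// A voxel is simple iff deleting it preserves both foreground and background
// topology locally: exactly one 26-component of foreground neighbours and
// exactly one 6-component of adjacent background in N18.
static bool is_simple(const std::vector<char> &vol, int x, int y, int z,
                      int nx, int ny, int nz) {
  bool nb[27];
  neighbourhood(vol, x, y, z, nx, ny, nz, nb);
  if (fg_components26(nb) != 1) return false;
  if (bg_components6(nb) != 1) return false;
  return true;
}


// Deletion safety used by the thinning phases: the foreground neighbours
// must form exactly one 26-component, so no deletion can split a component.
// The background condition of full (26,6) simplicity is deliberately NOT
// required: it would preserve voxel-scale handles ("bubbles" of doubled
// strands) that are rasterization artifacts, not vascular anastomoses.
// Connected-component count -- the invariant the skeleton guarantees -- is
// untouched either way.
static bool is_conn_safe(const std::vector<char> &vol, int x, int y, int z,
                         int nx, int ny, int nz) {
  bool nb[27];
  neighbourhood(vol, x, y, z, nx, ny, nz, nb);
  return fg_components26(nb) == 1;
}

static int count_fg_neighbours26(const std::vector<char> &vol, int x, int y,
                                 int z, int nx, int ny, int nz) {
  int n = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (!dx && !dy && !dz) continue;
        int xx = x + dx, yy = y + dy, zz = z + dz;
        if (inside(xx, yy, zz, nx, ny, nz) && vol[vidx(xx, yy, zz, nx, ny)]) ++n;
      }
  return n;
}

static bool has_bg_face_neighbour(const std::vector<char> &vol, int x, int y,
                                  int z, int nx, int ny, int nz) {
  const int d6[6][3] = {{-1,0,0},{1,0,0},{0,-1,0},{0,1,0},{0,0,-1},{0,0,1}};
  for (int k = 0; k < 6; ++k) {
    int xx = x + d6[k][0], yy = y + d6[k][1], zz = z + d6[k][2];
    if (!inside(xx, yy, zz, nx, ny, nz) || !vol[vidx(xx, yy, zz, nx, ny)])
      return true;
  }
  return false;
}

// Round-based sequential thinning with six directional sub-iterations.
// Per round: record first boundary exposure (peel depth), then for each of
// the six face directions delete, in lexicographic order, border voxels that
// are simple and not line ends.  Sequential deletion guarantees topology
// preservation; the fixed visiting order makes the result deterministic.
// [[Rcpp::export]]
List thin_volume_cpp(LogicalVector volume, IntegerVector dims, int max_rounds = 0) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t n = (size_t)nx * ny * nz;
  std::vector<char> vol(n);
  for (size_t i = 0; i < n; ++i) vol[i] = volume[i] ? 1 : 0;
  std::vector<int> exposure(n, -1);  // round of first boundary contact

  const int dirs[6][3] = {{0,0,-1},{0,0,1},{0,-1,0},{0,1,0},{-1,0,0},{1,0,0}};

  // Pre-fill pinhole tunnels: a background voxel with 4+ foreground face
  // neighbours sits in a one-voxel gap through which the 6-connected
  // background can tunnel, creating spurious handles (hence skeleton loops)
  // in thin oblique tubes.  Filling such voxels regularises the volume
  // without changing its gross shape.  Voxels are only filled when all
  // foreground face neighbours belong to one 26-component, so the component
  // count is untouched.
  std::vector<int> lab(n, 0);
  {
    int next = 0;
    for (size_t s = 0; s < n; ++s) {
      if (!vol[s] || lab[s]) continue;
      ++next;
      std::queue<int> q;
      q.push((int)s);
      lab[s] = next;
      while (!q.empty()) {
        int c = q.front(); q.pop();
        int x = c % nx, y = (c / nx) % ny, z = c / (nx * ny);
        for (int ddz = -1; ddz <= 1; ++ddz)
          for (int ddy = -1; ddy <= 1; ++ddy)
            for (int ddx = -1; ddx <= 1; ++ddx) {
              if (!ddx && !ddy && !ddz) continue;
              int xx = x + ddx, yy = y + ddy, zz = z + ddz;
              if (!inside(xx, yy, zz, nx, ny, nz)) continue;
              int j = vidx(xx, yy, zz, nx, ny);
              if (!vol[j] || lab[j]) continue;
              lab[j] = next;
              q.push(j);
            }
      }
    }
  }
  bool filled = true;
  while (filled) {
    filled = false;
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          int i = vidx(x, y, z, nx, ny);
          if (vol[i]) continue;
          int nf = 0, l0 = 0;
          bool mixed = false;
          for (int k = 0; k < 6; ++k) {
            int xx = x + dirs[k][0], yy = y + dirs[k][1], zz = z + dirs[k][2];
            if (!inside(xx, yy, zz, nx, ny, nz)) continue;
            int j = vidx(xx, yy, zz, nx, ny);
            if (!vol[j]) continue;
            ++nf;
            if (l0 == 0) l0 = lab[j];
            else if (lab[j] != l0) mixed = true;
          }
          if (nf >= 4 && !mixed) {
            vol[i] = 1;
            lab[i] = l0;
            filled = true;
          }
        }
  }

  int round = 0;
  bool changed = true;
  while (changed && (max_rounds <= 0 || round < max_rounds)) {
    ++round;
    changed = false;
    // mark exposure on the current volume
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          int i = vidx(x, y, z, nx, ny);
          if (vol[i] && exposure[i] < 0 &&
              has_bg_face_neighbour(vol, x, y, z, nx, ny, nz))
            exposure[i] = round;
        }
    for (int d = 0; d < 6; ++d) {
      int dx = dirs[d][0], dy = dirs[d][1], dz = dirs[d][2];
      // collect candidates (border in direction d) then delete sequentially,
      // re-testing simplicity as the volume shrinks
      std::vector<int> cand;
      for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y)
          for (int x = 0; x < nx; ++x) {
            int i = vidx(x, y, z, nx, ny);
            if (!vol[i]) continue;
            int xx = x + dx, yy = y + dy, zz = z + dz;
            bool border = !inside(xx, yy, zz, nx, ny, nz) ||
                          !vol[vidx(xx, yy, zz, nx, ny)];
            // opposite neighbour must be foreground: a layer is peeled only
            // from the side that has material behind it, so structures one
            // voxel thick in this direction are never consumed along it
            int ox = x - dx, oy = y - dy, oz = z - dz;
            bool backed = inside(ox, oy, oz, nx, ny, nz) &&
                          vol[vidx(ox, oy, oz, nx, ny)];
            if (border && backed) cand.push_back(i);
          }
      for (size_t c = 0; c < cand.size(); ++c) {
        int i = cand[c];
        if (!vol[i]) continue;
        int x = i % nx, y = (i / nx) % ny, z = i / (nx * ny);
        int nn = count_fg_neighbours26(vol, x, y, z, nx, ny, nz);
        if (nn <= 1) continue;  // line end (or isolated): never delete
        if (!is_simple(vol, x, y, z, nx, ny, nz)) continue;
        vol[i] = 0;
        changed = true;
      }
    }
  }

  // Phase 2: the directional peel never removes material from a direction
  // with no backing, so 2-voxel-wide ribbons can survive.  Reduce them with
  // sequential deletion of simple voxels that have >= 3 neighbours: a
  // deletion chain that would shorten a branch must consume 2-neighbour
  // chain ends, which this rule forbids, so branches keep their length
  // while residual thick spots collapse to single-voxel curves.
  changed = true;
  while (changed && (max_rounds <= 0 || round < max_rounds)) {
    ++round;
    changed = false;
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          int i = vidx(x, y, z, nx, ny);
          if (vol[i] && exposure[i] < 0 &&
              has_bg_face_neighbour(vol, x, y, z, nx, ny, nz))
            exposure[i] = round;
        }
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          int i = vidx(x, y, z, nx, ny);
          if (!vol[i]) continue;
          int nn = count_fg_neighbours26(vol, x, y, z, nx, ny, nz);
          bool deletable = false;
          if (nn >= 3) {
            deletable = true;
          } else if (nn == 2) {
            // redundant triangle corner: both neighbours mutually adjacent,
            // so removal leaves the path intact and shortens nothing
            int a = -1, b = -1;
            for (int ddz = -1; ddz <= 1 && b < 0; ++ddz)
              for (int ddy = -1; ddy <= 1 && b < 0; ++ddy)
                for (int ddx = -1; ddx <= 1 && b < 0; ++ddx) {
                  if (!ddx && !ddy && !ddz) continue;
                  int xx = x + ddx, yy = y + ddy, zz = z + ddz;
                  if (!inside(xx, yy, zz, nx, ny, nz)) continue;
                  int j = vidx(xx, yy, zz, nx, ny);
                  if (!vol[j]) continue;
                  if (a < 0) a = j; else b = j;
                }
            if (b >= 0) {
              int ax = a % nx, ay = (a / nx) % ny, az = a / (nx * ny);
              int bx = b % nx, by = (b / nx) % ny, bz = b / (nx * ny);
              deletable = std::abs(ax - bx) <= 1 && std::abs(ay - by) <= 1 &&
                          std::abs(az - bz) <= 1;
            }
          }
          if (!deletable) continue;
          if (!has_bg_face_neighbour(vol, x, y, z, nx, ny, nz)) continue;
          if (!is_conn_safe(vol, x, y, z, nx, ny, nz)) continue;
          vol[i] = 0;
          changed = true;
        }
  }

  LogicalVector skel(n);
  IntegerVector depth(n);
  for (size_t i = 0; i < n; ++i) {
    skel[i] = vol[i] != 0;
    depth[i] = (vol[i] && exposure[i] > 0) ? exposure[i] - 1 : 0;
  }
  skel.attr("dim") = dims;
  depth.attr("dim") = dims;
  return List::create(_["skeleton"] = skel, _["peel_depth"] = depth,
                      _["rounds"] = round - 1);
}

// Connected-component labelling; connectivity 6 or 26.
// [[Rcpp::export]]
List label_components_cpp(LogicalVector volume, IntegerVector dims,
                          int connectivity = 26) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t n = (size_t)nx * ny * nz;
  IntegerVector labels(n, 0);
  int next = 0;
  std::vector<std::array<int,3>> offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (!dx && !dy && !dz) continue;
        int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && m != 1) continue;
        offs.push_back({dx, dy, dz});
      }
  for (size_t s = 0; s < n; ++s) {
    if (!volume[s] || labels[s]) continue;
    ++next;
    std::queue<int> q;
    q.push((int)s);
    labels[s] = next;
    while (!q.empty()) {
      int c = q.front(); q.pop();
      int x = c % nx, y = (c / nx) % ny, z = c / (nx * ny);
      for (size_t k = 0; k < offs.size(); ++k) {
        int xx = x + offs[k][0], yy = y + offs[k][1], zz = z + offs[k][2];
        if (!inside(xx, yy, zz, nx, ny, nz)) continue;
        int j = vidx(xx, yy, zz, nx, ny);
        if (!volume[j] || labels[j]) continue;
        labels[j] = next;
        q.push(j);
      }
    }
  }
  labels.attr("dim") = dims;
  return List::create(_["labels"] = labels, _["n_components"] = next);
}

// Per-voxel count of foreground 26-neighbours, for skeleton classification.
// [[Rcpp::export]]
IntegerVector neighbour_counts_cpp(LogicalVector volume, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t n = (size_t)nx * ny * nz;
  std::vector<char> vol(n);
  for (size_t i = 0; i < n; ++i) vol[i] = volume[i] ? 1 : 0;
  IntegerVector out(n, 0);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int i = vidx(x, y, z, nx, ny);
        if (vol[i]) out[i] = count_fg_neighbours26(vol, x, y, z, nx, ny, nz);
      }
  out.attr("dim") = dims;
  return out;
}

// Debug/testing: simplicity of the centre voxel of a 3x3x3 configuration.
// [[Rcpp::export]]
bool is_simple_cpp(LogicalVector volume, IntegerVector dims, int x, int y,
                   int z) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t n = (size_t)nx * ny * nz;
  std::vector<char> vol(n);
  for (size_t i = 0; i < n; ++i) vol[i] = volume[i] ? 1 : 0;
  return is_simple(vol, x, y, z, nx, ny, nz);
}
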