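// 3D topology-preserving thinning: 6-subiteration border-sequential scheme.
// A voxel is deletable when it is simple (removal preserves both the
// 26-connectivity of the foreground and the 6-connectivity of the background)
// and not a curve endpoint. Simplicity is checked by the connectivity-number
// characterization: exactly one 26-connected foreground component in the
// 26-neighborhood, and exactly one 6-connected background component in the
// 18-neighborhood that is 6-adjacent to the center.
#include <Rcpp.h>
#include <vector>
#include <cstring>
using namespace Rcpp;

namespace {

// offsets of the 3x3x3 neighborhood, index n = (dx+1) + 3*(dy+1) + 9*(dz+1)
inline int noff(int dx, int dy, int dz) { return (dx + 1) + 3 * (dy + 1) + 9 * (dz + 1); }

struct NeighborhoodTables {
  // adjacency lists among the 27 cells (center excluded from components)
  std::vector<int> adj26[27];
  std::vector<int> adj6[27];
  bool in18[27];
  bool face[27]; // 6-adjacent to center
  NeighborhoodTables() {
    int d[27][3];
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          int n = noff(dx, dy, dz);
          d[n][0] = dx; d[n][1] = dy; d[n][2] = dz;
          int nz = (dx != 0) + (dy != 0) + (dz != 0);
          in18[n] = (nz >= 1 && nz <= 2);
          face[n] = (nz == 1);
        }
    for (int a = 0; a < 27; ++a) {
      if (a == 13) continue;
      for (int b = 0; b < 27; ++b) {
        if (b == 13 || b == a) continue;
        int ax = std::abs(d[a][0] - d[b][0]);
        int ay = std::abs(d[a][1] - d[b][1]);
        int az = std::abs(d[a][2] - d[b][2]);
        if (ax <= 1 && ay <= 1 && az <= 1) adj26[a].push_back(b);
        if (ax + ay + az == 1) adj6[a].push_back(b);
      }
    }
  }
};

const NeighborhoodTables TBL;

// number of 26-connected foreground components among the 26 neighbors
inline int fg_components26(const bool nb[27]) {
  bool seen[27] = {false};
  int ncomp = 0, stack[27];
  for (int s = 0; s < 27; ++s) {
    if (s == 13 || !nb[s] || seen[s]) continue;
    ++ncomp;
    int top = 0;
    stack[top++] = s; seen[s] = true;
    while (top) {
      int v = stack[--top];
      for (int w : TBL.adj26[v])
        if (nb[w] && !seen[w]) { seen[w] = true; stack[top++] = w; }
    }
  }
  return ncomp;
}

// number of 6-connected background components in N18 touching a face neighbor
inline int bg_components6(const bool nb[27]) {
  bool seen[27] = {false};
  int ncomp = 0, stack[27];
  for (int s = 0; s < 27; ++s) {
    if (!TBL.face[s] || nb[s] || seen[s]) continue; // seed only at background face cells
    ++ncomp;
    int top = 0;
    stack[top++] = s; seen[s] = true;
    while (top) {
      int v = stack[--top];
      for (int w : TBL.adj6[v])
        if (TBL.in18[w] && !nb[w] && !seen[w]) { seen[w] = true; stack[top++] = w; }
    }
  }
  return ncomp;
}

struct Vol {
  std::vector<unsigned char> v;
  int nx, ny, nz;
  inline bool at(int x, int y, int z) const {
    if (x < 0 || y < 0 || z < 0 || x >= nx || y >= ny || z >= nz) return false;
    return v[(size_t)x + (size_t)nx * ((size_t)y + (size_t)ny * z)] != 0;
  }
  inline void set(int x, int y, int z, bool b) {
    v[(size_t)x + (size_t)nx * ((size_t)y + (size_t)ny * z)] = b ? 1 : 0;
  }
};

inline void gather(const Vol& V, int x, int y, int z, bool nb[27]) {
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx)
        nb[noff(dx, dy, dz)] = V.at(x + dx, y + dy, z + dz);
}

inline int count26(const bool nb[27]) {
  int c = 0;
  for (int i = 0; i < 27; ++i) if (i != 13 && nb[i]) ++c;
  return c;
}

inline bool is_simple(const bool nb[27]) {
  return fg_components26(nb) == 1 && bg_components6(nb) == 1;
}

} // namespace

// [[Rcpp::export(name = ".thin_volume_cpp")]]
LogicalVector thin_volume_cpp(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  Vol V;
  V.nx = nx; V.ny = ny; V.nz = nz;
  V.v.resize((size_t)nx * ny * nz);
  for (R_xlen_t i = 0; i < mask.size(); ++i) V.v[i] = mask[i] ? 1 : 0;

  // the six border directions, fixed order for determinism: U, D, N, S, E, W
  const int dir[6][3] = {{0,0,-1},{0,0,1},{0,-1,0},{0,1,0},{-1,0,0},{1,0,0}};

  std::vector<int> cand;
  bool changed = true;
  bool nb[27];
  while (changed) {
    changed = false;
    for (int s = 0; s < 6; ++s) {
      cand.clear();
      for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y)
          for (int x = 0; x < nx; ++x) {
            if (!V.at(x, y, z)) continue;
            if (V.at(x + dir[s][0], y + dir[s][1], z + dir[s][2])) continue; // not border in s
            gather(V, x, y, z, nb);
            if (count26(nb) <= 1) continue; // endpoint preserved
            if (!is_simple(nb)) continue;
            cand.push_back(x); cand.push_back(y); cand.push_back(z);
          }
      // sequential deletion with re-check keeps the result thin and topology-safe
      for (size_t k = 0; k < cand.size(); k += 3) {
        int x = cand[k], y = cand[k + 1], z = cand[k + 2];
        gather(V, x, y, z, nb);
        if (count26(nb) <= 1) continue;
        if (!is_simple(nb)) continue;
        V.set(x, y, z, false);
        changed = true;
      }
    }
  }

  LogicalVector out((R_xlen_t)nx * ny * nz);
  for (R_xlen_t i = 0; i < out.size(); ++i) out[i] = V.v[i] != 0;
  out.attr("dim") = dims;
  return out;
}

// [[Rcpp::export(name = ".is_simple_point_cpp")]]
bool is_simple_point_cpp(LogicalVector nbhd) {
  bool nb[27];
  for (int i = 0; i < 27; ++i) nb[i] = nbhd[i] != 0;
  return is_simple(nb);
}
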