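#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Voxel kernels shared by the segmentation and hole-filling stages.
// All masks are logical vectors in R array (column-major) order with
// dimensions dim = (nx, ny, nz); offsets is a k x 3 integer matrix of
// neighbourhood displacements in voxel units.

static inline int64_t vidx(int x, int y, int z, int nx, int ny) {
  return (int64_t)x + (int64_t)nx * ((int64_t)y + (int64_t)ny * (int64_t)z);
}

// Breadth-first flood over the admissibility graph: voxels in `seeds` are
// always included; a voxel is added when it is `admissible` and adjacent
// (via `offsets`) to an already-included voxel.  Result is independent of
// traversal order because admissibility is fixed in advance.
// [[Rcpp::export(name = ".flood_from_seeds")]]
LogicalVector flood_from_seeds(LogicalVector admissible, LogicalVector seeds,
                               IntegerVector dim, IntegerMatrix offsets) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int64_t n = (int64_t)nx * ny * nz;
  if (admissible.size() != n || seeds.size() != n)
    stop("mask size does not match dimensions");
  std::vector<char> vis(n, 0);
  std::vector<int64_t> queue;
  queue.reserve(1024);
  for (int64_t i = 0; i < n; ++i) {
    if (seeds[i]) { vis[i] = 1; queue.push_back(i); }
  }
  const int k = offsets.nrow();
  std::vector<int> ox(k), oy(k), oz(k);
  for (int j = 0; j < k; ++j) {
    ox[j] = offsets(j, 0); oy[j] = offsets(j, 1); oz[j] = offsets(j, 2);
  }
  size_t head = 0;
  while (head < queue.size()) {
    const int64_t cur = queue[head++];
    const int x = (int)(cur % nx);
    const int y = (int)((cur / nx) % ny);
    const int z = (int)(cur / ((int64_t)nx * ny));
    for (int j = 0; j < k; ++j) {
      const int xx = x + ox[j], yy = y + oy[j], zz = z + oz[j];
      if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
        continue;
      const int64_t ni = vidx(xx, yy, zz, nx, ny);
      if (!vis[ni] && admissible[ni]) { vis[ni] = 1; queue.push_back(ni); }
    }
  }
  LogicalVector out(n);
  for (int64_t i = 0; i < n; ++i) out[i] = vis[i] != 0;
  return out;
}

// [[Rcpp::export(name = ".dilate_mask")]]
LogicalVector dilate_mask(LogicalVector mask, IntegerVector dim,
                          IntegerMatrix offsets) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int64_t n = (int64_t)nx * ny * nz;
  if (mask.size() != n) stop("mask size does not match dimensions");
  std::vector<char> out(n, 0);
  const int k = offsets.nrow();
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const int64_t i = vidx(x, y, z, nx, ny);
        if (!mask[i]) continue;
        for (int j = 0; j < k; ++j) {
          const int xx = x + offsets(j, 0), yy = y + offsets(j, 1),
                    zz = z + offsets(j, 2);
          if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
            continue;
          out[vidx(xx, yy, zz, nx, ny)] = 1;
        }
      }
  LogicalVector res(n);
  for (int64_t i = 0; i < n; ++i) res[i] = out[i] != 0;
  return res;
}

// Erosion; voxels outside the volume count as foreground (`outside = TRUE`)
// so that closing remains extensive at the volume border.
// [[Rcpp::export(name = ".erode_mask")]]
LogicalVector erode_mask(LogicalVector mask, IntegerVector dim,
                         IntegerMatrix offsets, bool outside) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int64_t n = (int64_t)nx * ny * nz;
  if (mask.size() != n) stop("mask size does not match dimensions");
  LogicalVector out(n);
  const int k = offsets.nrow();
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const int64_t i = vidx(x, y, z, nx, ny);
        bool keep = mask[i] != 0;
        for (int j = 0; keep && j < k; ++j) {
          const int xx = x + offsets(j, 0), yy = y + offsets(j, 1),
                    zz = z + offsets(j, 2);
          if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz) {
            if (!outside) keep = false;
            continue;
          }
          if (!mask[vidx(xx, yy, zz, nx, ny)]) keep = false;
        }
        out[i] = keep;
      }
  return out;
}

// Connected-component labelling over `offsets` adjacency; labels start at 1
// in scan order; 0 = background.
// [[Rcpp::export(name = ".label_components")]]
IntegerVector label_components(LogicalVector mask, IntegerVector dim,
                               IntegerMatrix offsets) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int64_t n = (int64_t)nx * ny * nz;
  if (mask.size() != n) stop("mask size does not match dimensions");
  IntegerVector lab(n, 0);
  const int k = offsets.nrow();
  std::vector<int64_t> queue;
  int next = 0;
  for (int64_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    queue.clear();
    queue.push_back(s);
    size_t head = 0;
    while (head < queue.size()) {
      const int64_t cur = queue[head++];
      const int x = (int)(cur % nx);
      const int y = (int)((cur / nx) % ny);
      const int z = (int)(cur / ((int64_t)nx * ny));
      for (int j = 0; j < k; ++j) {
        const int xx = x + offsets(j, 0), yy = y + offsets(j, 1),
                  zz = z + offsets(j, 2);
        if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
          continue;
        const int64_t ni = vidx(xx, yy, zz, nx, ny);
        if (mask[ni] && lab[ni] == 0) { lab[ni] = next; queue.push_back(ni); }
      }
    }
  }
  return lab;
}
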