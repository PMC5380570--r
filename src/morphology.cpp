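#include <Rcpp.h>
#include <vector>
#include <array>
#include <queue>
using namespace Rcpp;

// 3-D connected-component labeling (26-connectivity) by BFS.
// mask: logical vector in column-major order with dims (nx, ny, nz).
// Returns integer labels, 0 for background, components numbered from 1.
// [[Rcpp::export(name = ".label_components_3d")]]
IntegerVector label_components_3d(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector labels(n, 0);
  int next = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || labels[s] != 0) continue;
    labels[s] = ++next;
    q.push(s);
    while (!q.empty()) {
      R_xlen_t v = q.front(); q.pop();
      int x = (int)(v % nx);
      int y = (int)((v / nx) % ny);
      int z = (int)(v / ((R_xlen_t)nx * ny));
      for (int dz = -1; dz <= 1; ++dz) {
        int zz = z + dz; if (zz < 0 || zz >= nz) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          int yy = y + dy; if (yy < 0 || yy >= ny) continue;
          for (int dx = -1; dx <= 1; ++dx) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            int xx = x + dx; if (xx < 0 || xx >= nx) continue;
            R_xlen_t w = (R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx;
            if (mask[w] && labels[w] == 0) { labels[w] = next; q.push(w); }
          }
        }
      }
    }
  }
  labels.attr("n_components") = next;
  return labels;
}

static std::vector<std::array<int,3>> ball_offsets(int r) {
  std::vector<std::array<int,3>> off;
  for (int dz = -r; dz <= r; ++dz)
    for (int dy = -r; dy <= r; ++dy)
      for (int dx = -r; dx <= r; ++dx)
        if (dx*dx + dy*dy + dz*dz <= r*r)
          off.push_back({dx, dy, dz});
  return off;
}

// Binary dilation (op = 0) or erosion (op = 1) with a voxel ball of
// radius r.  Border handling: out-of-volume neighbors count as background,
// so erosion shrinks the mask at the volume faces.
// [[Rcpp::export(name = ".morph_ball_3d")]]
LogicalVector morph_ball_3d(LogicalVector mask, IntegerVector dims,
                            int r, int op) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector out(n);
  std::vector<std::array<int,3>> off = ball_offsets(r);
  for (int z = 0; z < nz; ++z) {
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) {
        R_xlen_t v = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx + x;
        bool hit = (op == 1);  // erosion: all neighbors must be set
        for (size_t k = 0; k < off.size(); ++k) {
          int xx = x + off[k][0], yy = y + off[k][1], zz = z + off[k][2];
          bool inside = xx >= 0 && xx < nx && yy >= 0 && yy < ny &&
                        zz >= 0 && zz < nz;
          bool val = inside &&
            mask[(R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx];
          if (op == 0) { if (val) { hit = true; break; } }
          else         { if (!val) { hit = false; break; } }
        }
        out[v] = hit;
      }
    }
  }
  return out;
}
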