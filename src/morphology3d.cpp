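#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 3D binary morphology and 26-connected labelling on logical arrays stored
// column-major as (y, x, z).  Structuring elements arrive as k x 3 integer
// offset matrices (dy, dx, dz) built in R from physical voxel sizes, so the
// anisotropy between lateral pitch and axial step is handled upstream.

static inline int idx3(int y, int x, int z, int ny, int nx) {
  return y + ny * (x + nx * z);
}

// [[Rcpp::export(name = ".erode3d")]]
LogicalVector erode3d(LogicalVector vol, IntegerVector dims, IntegerMatrix off) {
  const int ny = dims[0], nx = dims[1], nz = dims[2];
  const int k = off.nrow();
  LogicalVector out(vol.size());
  for (int z = 0; z < nz; ++z) {
    for (int x = 0; x < nx; ++x) {
      for (int y = 0; y < ny; ++y) {
        const int i = idx3(y, x, z, ny, nx);
        if (!vol[i]) { out[i] = FALSE; continue; }
        bool keep = true;
        for (int j = 0; j < k; ++j) {
          const int yy = y + off(j, 0), xx = x + off(j, 1), zz = z + off(j, 2);
          // voxels outside the stack count as background: erosion shrinks at borders
          if (yy < 0 || yy >= ny || xx < 0 || xx >= nx || zz < 0 || zz >= nz ||
              !vol[idx3(yy, xx, zz, ny, nx)]) { keep = false; break; }
        }
        out[i] = keep;
      }
    }
  }
  return out;
}

// [[Rcpp::export(name = ".dilate3d")]]
LogicalVector dilate3d(LogicalVector vol, IntegerVector dims, IntegerMatrix off) {
  const int ny = dims[0], nx = dims[1], nz = dims[2];
  const int k = off.nrow();
  LogicalVector out(vol.size());
  for (int z = 0; z < nz; ++z) {
    for (int x = 0; x < nx; ++x) {
      for (int y = 0; y < ny; ++y) {
        const int i = idx3(y, x, z, ny, nx);
        if (!vol[i]) continue;
        // scatter: symmetric elements make scatter == gather with reflection
        for (int j = 0; j < k; ++j) {
          const int yy = y + off(j, 0), xx = x + off(j, 1), zz = z + off(j, 2);
          if (yy >= 0 && yy < ny && xx >= 0 && xx < nx && zz >= 0 && zz < nz)
            out[idx3(yy, xx, zz, ny, nx)] = TRUE;
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export(name = ".label3d")]]
IntegerVector label3d(LogicalVector vol, IntegerVector dims) {
  const int ny = dims[0], nx = dims[1], nz = dims[2];
  IntegerVector lab(vol.size(), 0);
  int next = 0;
  std::vector<int> stack;
  stack.reserve(1024);
  for (int z = 0; z < nz; ++z) {
    for (int x = 0; x < nx; ++x) {
      for (int y = 0; y < ny; ++y) {
        const int i0 = idx3(y, x, z, ny, nx);
        if (!vol[i0] || lab[i0]) continue;
        ++next;
        lab[i0] = next;
        stack.push_back(i0);
        while (!stack.empty()) {
          const int i = stack.back();
          stack.pop_back();
          const int zi = i / (ny * nx), rem = i % (ny * nx);
          const int xi = rem / ny, yi = rem % ny;
          for (int dz = -1; dz <= 1; ++dz) {
            const int zz = zi + dz;
            if (zz < 0 || zz >= nz) continue;
            for (int dx = -1; dx <= 1; ++dx) {
              const int xx = xi + dx;
              if (xx < 0 || xx >= nx) continue;
              for (int dy = -1; dy <= 1; ++dy) {
                const int yy = yi + dy;
                if (yy < 0 || yy >= ny) continue;
                const int j = idx3(yy, xx, zz, ny, nx);
                if (vol[j] && !lab[j]) {
                  lab[j] = next;
                  stack.push_back(j);
                }
              }
            }
          }
        }
      }
    }
  }
  lab.attr("n") = next;
  return lab;
}
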