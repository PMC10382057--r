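#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// All kernels take a quantized volume as an integer vector in R array order
// (column-major, x fastest), with dim = (nx, ny, nz). Values 1..L inside the
// mask, 0 outside. Offsets are given as an n x 3 integer matrix of voxel
// steps; callers pass the 13 unique 3D directions (or the 4 in-plane ones).

static inline int idx3(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// Co-occurrence counts: one ordered count per (voxel, offset) pair where both
// ends are in-mask. Symmetrization happens in R.
// [[Rcpp::export]]
IntegerMatrix cpp_cooccurrence(IntegerVector lab, IntegerVector dim, int L,
                               IntegerMatrix offsets) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  IntegerMatrix counts(L, L);
  int noff = offsets.nrow();
  for (int o = 0; o < noff; ++o) {
    int dx = offsets(o, 0), dy = offsets(o, 1), dz = offsets(o, 2);
    for (int z = 0; z < nz; ++z) {
      int z2 = z + dz;
      if (z2 < 0 || z2 >= nz) continue;
      for (int y = 0; y < ny; ++y) {
        int y2 = y + dy;
        if (y2 < 0 || y2 >= ny) continue;
        for (int x = 0; x < nx; ++x) {
          int x2 = x + dx;
          if (x2 < 0 || x2 >= nx) continue;
          int a = lab[idx3(x, y, z, nx, ny)];
          if (a <= 0) continue;
          int b = lab[idx3(x2, y2, z2, nx, ny)];
          if (b <= 0) continue;
          counts(a - 1, b - 1)++;
        }
      }
    }
  }
  return counts;
}

// Run-length counts: a run is a maximal sequence of equal-level in-mask
// voxels along one direction. Counted once (started where the previous voxel
// along the direction is absent/different), summed over the given directions.
// [[Rcpp::export]]
IntegerMatrix cpp_runlength(IntegerVector lab, IntegerVector dim, int L,
                            IntegerMatrix offsets) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int maxlen = std::max(nx, std::max(ny, nz));
  IntegerMatrix counts(L, maxlen);
  int noff = offsets.nrow();
  for (int o = 0; o < noff; ++o) {
    int dx = offsets(o, 0), dy = offsets(o, 1), dz = offsets(o, 2);
    for (int z = 0; z < nz; ++z) {
      for (int y = 0; y < ny; ++y) {
        for (int x = 0; x < nx; ++x) {
          int a = lab[idx3(x, y, z, nx, ny)];
          if (a <= 0) continue;
          // run start: predecessor out of grid, out of mask, or other level
          int xp = x - dx, yp = y - dy, zp = z - dz;
          if (xp >= 0 && xp < nx && yp >= 0 && yp < ny && zp >= 0 && zp < nz &&
              lab[idx3(xp, yp, zp, nx, ny)] == a)
            continue;
          int len = 1;
          int xc = x + dx, yc = y + dy, zc = z + dz;
          while (xc >= 0 && xc < nx && yc >= 0 && yc < ny && zc >= 0 &&
                 zc < nz && lab[idx3(xc, yc, zc, nx, ny)] == a) {
            ++len;
            xc += dx; yc += dy; zc += dz;
          }
          if (len > maxlen) len = maxlen; // cannot happen; guard
          counts(a - 1, len - 1)++;
        }
      }
    }
  }
  return counts;
}

// Size-zone enumeration: connected components of equal-level in-mask voxels,
// 26-connected (or 8-connected within slices when planar). Returns a matrix
// with one row per zone: (level, size).
// [[Rcpp::export]]
IntegerMatrix cpp_zones(IntegerVector lab, IntegerVector dim, bool planar) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int n = nx * ny * nz;
  std::vector<char> seen(n, 0);
  std::vector<int> zl, zs, stack;
  for (int z = 0; z < nz; ++z) {
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) {
        int i0 = idx3(x, y, z, nx, ny);
        int a = lab[i0];
        if (a <= 0 || seen[i0]) continue;
        int size = 0;
        stack.clear();
        stack.push_back(i0);
        seen[i0] = 1;
        while (!stack.empty()) {
          int i = stack.back();
          stack.pop_back();
          ++size;
          int cx = i % nx, cy = (i / nx) % ny, cz = i / (nx * ny);
          int dzlo = planar ? 0 : -1, dzhi = planar ? 0 : 1;
          for (int dz = dzlo; dz <= dzhi; ++dz) {
            int z2 = cz + dz;
            if (z2 < 0 || z2 >= nz) continue;
            for (int dy = -1; dy <= 1; ++dy) {
              int y2 = cy + dy;
              if (y2 < 0 || y2 >= ny) continue;
              for (int dx = -1; dx <= 1; ++dx) {
                if (dx == 0 && dy == 0 && dz == 0) continue;
                int x2 = cx + dx;
                if (x2 < 0 || x2 >= nx) continue;
                int j = idx3(x2, y2, z2, nx, ny);
                if (!seen[j] && lab[j] == a) {
                  seen[j] = 1;
                  stack.push_back(j);
                }
              }
            }
          }
        }
        zl.push_back(a);
        zs.push_back(size);
      }
    }
  }
  IntegerMatrix out(zl.size(), 2);
  for (size_t k = 0; k < zl.size(); ++k) {
    out(k, 0) = zl[k];
    out(k, 1) = zs[k];
  }
  return out;
}

// Neighborhood gray-tone difference accumulators: for each in-mask voxel
// with at least one in-mask neighbor in the (2d+1)^3 - 1 cube, accumulate
// |level - mean(neighbor levels)| into s and count into nvec per level.
// [[Rcpp::export]]
NumericMatrix cpp_ngtdm(IntegerVector lab, IntegerVector dim, int L, int d) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericMatrix out(L, 2); // col 0: n_i, col 1: s_i
  // 3D integral images of the level values and the in-mask indicator give
  // each cubic neighborhood sum in O(1).
  int px = nx + 1, py = ny + 1, pz = nz + 1;
  std::vector<double> csum((size_t)px * py * pz, 0.0);
  std::vector<double> ccnt((size_t)px * py * pz, 0.0);
  auto P = [&](std::vector<double> &v, int x, int y, int z) -> double & {
    return v[(size_t)x + (size_t)px * ((size_t)y + (size_t)py * z)];
  };
  for (int z = 1; z <= nz; ++z) {
    for (int y = 1; y <= ny; ++y) {
      for (int x = 1; x <= nx; ++x) {
        int a = lab[idx3(x - 1, y - 1, z - 1, nx, ny)];
        double val = a > 0 ? a : 0.0;
        double cnt = a > 0 ? 1.0 : 0.0;
        P(csum, x, y, z) = val + P(csum, x - 1, y, z) + P(csum, x, y - 1, z) +
          P(csum, x, y, z - 1) - P(csum, x - 1, y - 1, z) -
          P(csum, x - 1, y, z - 1) - P(csum, x, y - 1, z - 1) +
          P(csum, x - 1, y - 1, z - 1);
        P(ccnt, x, y, z) = cnt + P(ccnt, x - 1, y, z) + P(ccnt, x, y - 1, z) +
          P(ccnt, x, y, z - 1) - P(ccnt, x - 1, y - 1, z) -
          P(ccnt, x - 1, y, z - 1) - P(ccnt, x, y - 1, z - 1) +
          P(ccnt, x - 1, y - 1, z - 1);
      }
    }
  }
  auto boxsum = [&](std::vector<double> &v, int x0, int y0, int z0, int x1,
                    int y1, int z1) {
    // inclusive voxel box [x0,x1] x [y0,y1] x [z0,z1], 0-based
    return P(v, x1 + 1, y1 + 1, z1 + 1) - P(v, x0, y1 + 1, z1 + 1) -
      P(v, x1 + 1, y0, z1 + 1) - P(v, x1 + 1, y1 + 1, z0) +
      P(v, x0, y0, z1 + 1) + P(v, x0, y1 + 1, z0) + P(v, x1 + 1, y0, z0) -
      P(v, x0, y0, z0);
  };
  for (int z = 0; z < nz; ++z) {
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) {
        int a = lab[idx3(x, y, z, nx, ny)];
        if (a <= 0) continue;
        int x0 = std::max(0, x - d), x1 = std::min(nx - 1, x + d);
        int y0 = std::max(0, y - d), y1 = std::min(ny - 1, y + d);
        int z0 = std::max(0, z - d), z1 = std::min(nz - 1, z + d);
        double sum = boxsum(csum, x0, y0, z0, x1, y1, z1) - a;
        double cnt = boxsum(ccnt, x0, y0, z0, x1, y1, z1) - 1.0;
        if (cnt > 0) {
          out(a - 1, 0) += 1.0;
          out(a - 1, 1) += std::fabs(a - sum / cnt);
        }
      }
    }
  }
  return out;
}

// Morphological erosion/dilation of a binary mask by a cubic structuring
// element of half-width r (3x3x3 cube for r = 1).
// [[Rcpp::export]]
LogicalVector cpp_morph(LogicalVector mask, IntegerVector dim, int r,
                        bool erode) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  LogicalVector out(mask.size());
  for (int z = 0; z < nz; ++z) {
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) {
        bool acc = erode;
        for (int dz = -r; dz <= r && acc == erode; ++dz) {
          int z2 = z + dz;
          for (int dy = -r; dy <= r && acc == erode; ++dy) {
            int y2 = y + dy;
            for (int dx = -r; dx <= r; ++dx) {
              int x2 = x + dx;
              bool v;
              if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 ||
                  z2 >= nz)
                v = false; // outside the grid counts as background
              else
                v = mask[idx3(x2, y2, z2, nx, ny)];
              if (erode && !v) { acc = false; break; }
              if (!erode && v) { acc = true; break; }
            }
          }
        }
        out[idx3(x, y, z, nx, ny)] = acc;
      }
    }
  }
  return out;
}
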