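#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Voxel arrays are column-major with dim = (nz, ny, nx): index
// (iz, iy, ix) lives at iz + nz * (iy + ny * ix).  Offsets matrices
// have one row per structuring-element / neighbourhood member, columns
// (dz, dy, dx).  Out-of-bounds voxels are background (false): erosion
// strips the stack faces, dilation cannot wrap.

static inline bool in_bounds(int z, int y, int x, int nz, int ny, int nx) {
  return z >= 0 && z < nz && y >= 0 && y < ny && x >= 0 && x < nx;
}

// [[Rcpp::export]]
LogicalVector cpp_dilate(LogicalVector mask, IntegerVector dim,
                         IntegerMatrix off) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const int m = off.nrow();
  LogicalVector out(mask.size());
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        bool hit = false;
        for (int k = 0; k < m && !hit; ++k) {
          int zz = z + off(k, 0), yy = y + off(k, 1), xx = x + off(k, 2);
          if (in_bounds(zz, yy, xx, nz, ny, nx) &&
              mask[zz + nz * (yy + ny * xx)])
            hit = true;
        }
        out[z + nz * (y + ny * x)] = hit;
      }
  return out;
}

// [[Rcpp::export]]
LogicalVector cpp_erode(LogicalVector mask, IntegerVector dim,
                        IntegerMatrix off) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const int m = off.nrow();
  LogicalVector out(mask.size());
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        bool all = true;
        for (int k = 0; k < m && all; ++k) {
          int zz = z + off(k, 0), yy = y + off(k, 1), xx = x + off(k, 2);
          if (!in_bounds(zz, yy, xx, nz, ny, nx) ||
              !mask[zz + nz * (yy + ny * xx)])
            all = false;
        }
        out[z + nz * (y + ny * x)] = all;
      }
  return out;
}

// Connected-component labeling by breadth-first search.  Seeds are
// visited in linear (raster) index order, so labels 1..K are assigned
// by the raster order of each component's first voxel.
// [[Rcpp::export]]
IntegerVector cpp_label(LogicalVector mask, IntegerVector dim,
                        IntegerMatrix off) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const int n = mask.size(), m = off.nrow();
  IntegerVector lab(n, 0);
  int next = 0;
  std::queue<int> q;
  for (int i = 0; i < n; ++i) {
    if (!mask[i] || lab[i] != 0) continue;
    ++next;
    lab[i] = next;
    q.push(i);
    while (!q.empty()) {
      int cur = q.front();
      q.pop();
      int z = cur % nz, rest = cur / nz;
      int y = rest % ny, x = rest / ny;
      for (int k = 0; k < m; ++k) {
        int zz = z + off(k, 0), yy = y + off(k, 1), xx = x + off(k, 2);
        if (!in_bounds(zz, yy, xx, nz, ny, nx)) continue;
        int j = zz + nz * (yy + ny * xx);
        if (mask[j] && lab[j] == 0) {
          lab[j] = next;
          q.push(j);
        }
      }
    }
  }
  return lab;
}

// Add anisotropic Gaussian intensity blobs to a stack, in place on a
// copy.  centers/sigmas are (n x 3) in um with columns (x, y, z);
// spacing is (dz, dy, dx) um; amps are the post-blur peak intensities.
// Each blob is rendered on a bounding box of +/- cutoff sigmas.
// [[Rcpp::export]]
NumericVector cpp_add_gaussians(NumericVector base, IntegerVector dim,
                                NumericVector spacing, NumericMatrix centers,
                                NumericMatrix sigmas, NumericVector amps,
                                double cutoff) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const double dz = spacing[0], dy = spacing[1], dx = spacing[2];
  NumericVector out = clone(base);
  for (int b = 0; b < centers.nrow(); ++b) {
    const double cx = centers(b, 0), cy = centers(b, 1), cz = centers(b, 2);
    const double sx = sigmas(b, 0), sy = sigmas(b, 1), sz = sigmas(b, 2);
    const double A = amps[b];
    int x0 = std::max(0, (int)std::floor((cx - cutoff * sx) / dx));
    int x1 = std::min(nx - 1, (int)std::ceil((cx + cutoff * sx) / dx));
    int y0 = std::max(0, (int)std::floor((cy - cutoff * sy) / dy));
    int y1 = std::min(ny - 1, (int)std::ceil((cy + cutoff * sy) / dy));
    int z0 = std::max(0, (int)std::floor((cz - cutoff * sz) / dz));
    int z1 = std::min(nz - 1, (int)std::ceil((cz + cutoff * sz) / dz));
    for (int x = x0; x <= x1; ++x) {
      double ex = (x * dx - cx) / sx;
      ex = std::exp(-0.5 * ex * ex);
      for (int y = y0; y <= y1; ++y) {
        double ey = (y * dy - cy) / sy;
        ey = std::exp(-0.5 * ey * ey);
        double axy = A * ex * ey;
        for (int z = z0; z <= z1; ++z) {
          double ez = (z * dz - cz) / sz;
          out[z + nz * (y + ny * x)] += axy * std::exp(-0.5 * ez * ez);
        }
      }
    }
  }
  return out;
}

// Separable 1D convolution along one axis (1 = z, 2 = y, 3 = x) with
// replicate edge handling; kernel length must be odd.
// [[Rcpp::export]]
NumericVector cpp_conv_axis(NumericVector a, IntegerVector dim,
                            NumericVector kern, int axis) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const int kl = kern.size(), h = kl / 2;
  NumericVector out(a.size());
  int nA = (axis == 1) ? nz : (axis == 2) ? ny : nx;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        double acc = 0.0;
        int pos = (axis == 1) ? z : (axis == 2) ? y : x;
        for (int k = 0; k < kl; ++k) {
          int p = pos + k - h;
          if (p < 0) p = 0;
          if (p >= nA) p = nA - 1;
          int zz = z, yy = y, xx = x;
          if (axis == 1) zz = p; else if (axis == 2) yy = p; else xx = p;
          acc += kern[k] * a[zz + nz * (yy + ny * xx)];
        }
        out[z + nz * (y + ny * x)] = acc;
      }
  return out;
}
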