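// 3D image kernels for the segmentation pipeline.
// Volumes are passed as flat numeric vectors in R's column-major layout with
// dim = (nz, ny, nx), i.e. index(z,y,x) = z + nz*(y + ny*x).

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <deque>
#include <vector>

using namespace Rcpp;

static inline int idx3(int z, int y, int x, int nz, int ny) {
  return z + nz * (y + ny * x);
}

// [[Rcpp::export]]
NumericVector cpp_median3d(NumericVector vol, IntegerVector dim,
                           IntegerVector half) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const int hz = half[0], hy = half[1], hx = half[2];
  NumericVector out(vol.size());
  std::vector<double> buf;
  buf.reserve((2 * hz + 1) * (2 * hy + 1) * (2 * hx + 1));
  for (int x = 0; x < nx; ++x) {
    const int x0 = std::max(0, x - hx), x1 = std::min(nx - 1, x + hx);
    for (int y = 0; y < ny; ++y) {
      const int y0 = std::max(0, y - hy), y1 = std::min(ny - 1, y + hy);
      for (int z = 0; z < nz; ++z) {
        const int z0 = std::max(0, z - hz), z1 = std::min(nz - 1, z + hz);
        buf.clear();
        for (int xx = x0; xx <= x1; ++xx)
          for (int yy = y0; yy <= y1; ++yy)
            for (int zz = z0; zz <= z1; ++zz)
              buf.push_back(vol[idx3(zz, yy, xx, nz, ny)]);
        std::sort(buf.begin(), buf.end());
        const size_t m = buf.size();
        double med = (m % 2 == 1) ? buf[m / 2]
                                  : 0.5 * (buf[m / 2 - 1] + buf[m / 2]);
        out[idx3(z, y, x, nz, ny)] = med;
      }
    }
  }
  return out;
}

// Sliding min/max over window [i-h, i+h] (clipped at borders), monotonic deque.
static void slide1d(const double* src, int n, int stride, int h, double* dst,
                    int dstride, bool ismax) {
  std::deque<int> dq;
  int pushed = -1;
  for (int i = 0; i < n; ++i) {
    const int upto = std::min(n - 1, i + h);
    for (int j = pushed + 1; j <= upto; ++j) {
      const double v = src[j * stride];
      while (!dq.empty()) {
        const double back = src[dq.back() * stride];
        if ((ismax && back <= v) || (!ismax && back >= v)) dq.pop_back();
        else break;
      }
      dq.push_back(j);
    }
    pushed = upto;
    while (dq.front() < i - h) dq.pop_front();
    dst[i * dstride] = src[dq.front() * stride];
  }
}

// Flat elliptical-disk min/max of one plane (ny x nx, column-major: y fastest).
// Decomposed as variable-width row filters followed by a column combine.
static void disk_filter_plane(const double* plane, int ny, int nx, double ry,
                              double rx, bool ismax, double* out,
                              std::vector<double>& rowbuf) {
  const int iry = (int)std::floor(ry + 1e-9);
  // half-width along x for each |dy|
  std::vector<int> hx(iry + 1);
  for (int dy = 0; dy <= iry; ++dy) {
    double f = (ry > 0) ? 1.0 - (double)dy * dy / (ry * ry) : 1.0;
    if (f < 0) f = 0;
    hx[dy] = (int)std::floor(rx * std::sqrt(f) + 1e-9);
  }
  // rowbuf[a][y][x]: row y filtered along x at half-width hx[a]
  rowbuf.resize((size_t)(iry + 1) * ny * nx);
  std::vector<double> row(nx), frow(nx);
  for (int y = 0; y < ny; ++y) {
    for (int x = 0; x < nx; ++x) row[x] = plane[y + ny * x];
    for (int a = 0; a <= iry; ++a) {
      slide1d(row.data(), nx, 1, hx[a], frow.data(), 1, ismax);
      double* dst = rowbuf.data() + (size_t)a * ny * nx;
      for (int x = 0; x < nx; ++x) dst[y + ny * x] = frow[x];
    }
  }
  const double init = ismax ? -HUGE_VAL : HUGE_VAL;
  for (int i = 0; i < ny * nx; ++i) out[i] = init;
  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) {
      double acc = init;
      for (int dy = -iry; dy <= iry; ++dy) {
        const int yy = y + dy;
        if (yy < 0 || yy >= ny) continue;
        const double v =
            rowbuf[(size_t)std::abs(dy) * ny * nx + yy + ny * x];
        if (ismax ? (v > acc) : (v < acc)) acc = v;
      }
      out[y + ny * x] = acc;
    }
  }
}

// Grayscale erosion/dilation with a flat ellipsoidal structuring element of
// voxel radii r = (rz, ry, rx). Border handling: shrinking window.
// [[Rcpp::export]]
NumericVector cpp_morph_ellipsoid(NumericVector vol, IntegerVector dim,
                                  NumericVector r, bool dilate) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const double rz = r[0], ry = r[1], rx = r[2];
  const int irz = (int)std::floor(rz + 1e-9);
  const size_t np = (size_t)ny * nx;
  const double init = dilate ? -HUGE_VAL : HUGE_VAL;
  NumericVector out(vol.size(), init);
  std::vector<double> plane(np), disk(np), rowbuf;
  for (int adz = 0; adz <= irz; ++adz) {
    double f = (rz > 0) ? 1.0 - (double)adz * adz / (rz * rz) : 1.0;
    if (f < 0) f = 0;
    const double s = std::sqrt(f);
    const double ry_d = ry * s, rx_d = rx * s;
    for (int zs = 0; zs < nz; ++zs) {
      for (int x = 0; x < nx; ++x)
        for (int y = 0; y < ny; ++y)
          plane[y + (size_t)ny * x] = vol[idx3(zs, y, x, nz, ny)];
      disk_filter_plane(plane.data(), ny, nx, ry_d, rx_d, dilate, disk.data(),
                        rowbuf);
      for (int sgn = 0; sgn < 2; ++sgn) {
        if (adz == 0 && sgn == 1) break;
        const int zt = sgn == 0 ? zs - adz : zs + adz;
        if (zt < 0 || zt >= nz) continue;
        for (int x = 0; x < nx; ++x)
          for (int y = 0; y < ny; ++y) {
            double& o = out[idx3(zt, y, x, nz, ny)];
            const double v = disk[y + (size_t)ny * x];
            if (dilate ? (v > o) : (v < o)) o = v;
          }
      }
    }
  }
  return out;
}

// Non-flat (ball kernel) grayscale opening of one plane = rolling-ball
// background estimate. Ball semi-axes (ry, rx) in pixels; cap height equals
// min(rx, ry) in intensity units (the usual pixel-units convention).
// Large balls are computed on a min-pooled grid and bilinearly upsampled.
// [[Rcpp::export]]
NumericMatrix cpp_rolling_ball_bg(NumericMatrix img, double ry, double rx) {
  const int ny = img.nrow(), nx = img.ncol();
  const int s = std::max(1, (int)std::floor(std::min(rx, ry) / 10.0));
  const int my = (ny + s - 1) / s, mx = (nx + s - 1) / s;
  NumericMatrix small(my, mx);
  for (int gy = 0; gy < my; ++gy)
    for (int gx = 0; gx < mx; ++gx) {
      double m = HUGE_VAL;
      for (int y = gy * s; y < std::min(ny, (gy + 1) * s); ++y)
        for (int x = gx * s; x < std::min(nx, (gx + 1) * s); ++x)
          m = std::min(m, img(y, x));
      small(gy, gx) = m;
    }
  const double rys = ry / s, rxs = rx / s;
  const double rh = std::min(rys, rxs);
  const int iry = (int)std::floor(rys + 1e-9), irx = (int)std::floor(rxs + 1e-9);
  // precompute ball heights over the elliptical support
  std::vector<std::vector<double>> ball(2 * iry + 1,
                                        std::vector<double>(2 * irx + 1, -1));
  for (int dy = -iry; dy <= iry; ++dy)
    for (int dx = -irx; dx <= irx; ++dx) {
      double q = 1.0;
      if (rys > 0) q -= (double)dy * dy / (rys * rys);
      if (rxs > 0) q -= (double)dx * dx / (rxs * rxs);
      if (q >= 0) ball[dy + iry][dx + irx] = rh * std::sqrt(q);
    }
  NumericMatrix ero(my, mx), bg(my, mx);
  for (int y = 0; y < my; ++y)
    for (int x = 0; x < mx; ++x) {
      double m = HUGE_VAL;
      for (int dy = -iry; dy <= iry; ++dy) {
        const int yy = y + dy;
        if (yy < 0 || yy >= my) continue;
        for (int dx = -irx; dx <= irx; ++dx) {
          const int xx = x + dx;
          if (xx < 0 || xx >= mx) continue;
          const double b = ball[dy + iry][dx + irx];
          if (b < 0) continue;
          m = std::min(m, small(yy, xx) - b);
        }
      }
      ero(y, x) = m;
    }
  for (int y = 0; y < my; ++y)
    for (int x = 0; x < mx; ++x) {
      double m = -HUGE_VAL;
      for (int dy = -iry; dy <= iry; ++dy) {
        const int yy = y + dy;
        if (yy < 0 || yy >= my) continue;
        for (int dx = -irx; dx <= irx; ++dx) {
          const int xx = x + dx;
          if (xx < 0 || xx >= mx) continue;
          const double b = ball[dy + iry][dx + irx];
          if (b < 0) continue;
          m = std::max(m, ero(yy, xx) + b);
        }
      }
      bg(y, x) = m;
    }
  NumericMatrix out(ny, nx);
  if (s == 1) {
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) out(y, x) = std::min(bg(y, x), img(y, x));
    return out;
  }
  for (int y = 0; y < ny; ++y) {
    double fy = ((double)y + 0.5) / s - 0.5;
    fy = std::min(std::max(fy, 0.0), (double)(my - 1));
    const int y0 = (int)fy, y1 = std::min(my - 1, y0 + 1);
    const double wy = fy - y0;
    for (int x = 0; x < nx; ++x) {
      double fx = ((double)x + 0.5) / s - 0.5;
      fx = std::min(std::max(fx, 0.0), (double)(mx - 1));
      const int x0 = (int)fx, x1 = std::min(mx - 1, x0 + 1);
      const double wx = fx - x0;
      const double v = (1 - wy) * ((1 - wx) * bg(y0, x0) + wx * bg(y0, x1)) +
                       wy * ((1 - wx) * bg(y1, x0) + wx * bg(y1, x1));
      out(y, x) = std::min(v, img(y, x));
    }
  }
  return out;
}

// Hysteresis thresholding: keep voxels >= lo that are 26-connected to a
// voxel >= hi.
// [[Rcpp::export]]
LogicalVector cpp_hysteresis3d(NumericVector vol, IntegerVector dim, double lo,
                               double hi) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = vol.size();
  std::vector<char> keep(n, 0);
  std::vector<int> stack;
  for (R_xlen_t i = 0; i < n; ++i)
    if (vol[i] >= hi) {
      keep[i] = 1;
      stack.push_back((int)i);
    }
  while (!stack.empty()) {
    const int i = stack.back();
    stack.pop_back();
    const int z = i % nz, y = (i / nz) % ny, x = i / (nz * ny);
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (dz == 0 && dy == 0 && dx == 0) continue;
          const int zz = z + dz, yy = y + dy, xx = x + dx;
          if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
            continue;
          const int j = idx3(zz, yy, xx, nz, ny);
          if (!keep[j] && vol[j] >= lo) {
            keep[j] = 1;
            stack.push_back(j);
          }
        }
  }
  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = keep[i] != 0;
  return out;
}

// 26-connected component labeling of a boolean volume.
// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dim) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = mask.size();
  IntegerVector lab(n, 0);
  std::vector<int> stack;
  int next = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || lab[i] != 0) continue;
    ++next;
    lab[i] = next;
    stack.push_back((int)i);
    while (!stack.empty()) {
      const int c = stack.back();
      stack.pop_back();
      const int z = c % nz, y = (c / nz) % ny, x = c / (nz * ny);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (dz == 0 && dy == 0 && dx == 0) continue;
            const int zz = z + dz, yy = y + dy, xx = x + dx;
            if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
              continue;
            const int j = idx3(zz, yy, xx, nz, ny);
            if (mask[j] && lab[j] == 0) {
              lab[j] = next;
              stack.push_back(j);
            }
          }
    }
  }
  return lab;
}
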