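#include <Rcpp.h>
using namespace Rcpp;

// Volumes are stored column-major (R array order): index = i + nx*(j + ny*k).
// All voxel coordinates here are 0-based continuous indices.

static inline int mirror_index(int i, int n) {
  // reflect about the edge voxel centers (mirror boundary, period 2n-2)
  if (n == 1) return 0;
  int p = 2 * n - 2;
  i = ((i % p) + p) % p;
  return (i < n) ? i : p - i;
}

static inline double cubic_kernel(double t) {
  // Catmull-Rom (a = -0.5): interpolating, reproduces linear functions exactly
  double at = std::fabs(t);
  if (at < 1.0) return 1.0 - 2.5 * at * at + 1.5 * at * at * at;
  if (at < 2.0) return 2.0 - 4.0 * at + 2.5 * at * at - 0.5 * at * at * at;
  return 0.0;
}

// [[Rcpp::export]]
NumericVector cpp_sample_tricubic(NumericVector vol, IntegerVector dims,
                                  NumericMatrix coords) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n = coords.nrow();
  NumericVector out(n);
  for (int q = 0; q < n; ++q) {
    double x = coords(q, 0), y = coords(q, 1), z = coords(q, 2);
    int ix = (int)std::floor(x), iy = (int)std::floor(y), iz = (int)std::floor(z);
    double fx = x - ix, fy = y - iy, fz = z - iz;
    double wx[4], wy[4], wz[4];
    for (int t = 0; t < 4; ++t) {
      wx[t] = cubic_kernel(fx - (t - 1));
      wy[t] = cubic_kernel(fy - (t - 1));
      wz[t] = cubic_kernel(fz - (t - 1));
    }
    double acc = 0.0;
    for (int c = 0; c < 4; ++c) {
      int kz = mirror_index(iz + c - 1, nz);
      for (int b = 0; b < 4; ++b) {
        int ky = mirror_index(iy + b - 1, ny);
        double wyz = wy[b] * wz[c];
        for (int a = 0; a < 4; ++a) {
          int kx = mirror_index(ix + a - 1, nx);
          acc += wx[a] * wyz * vol[kx + (size_t)nx * (ky + (size_t)ny * kz)];
        }
      }
    }
    out[q] = acc;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_sample_trilinear(NumericVector vol, IntegerVector dims,
                                   NumericMatrix coords, bool edge_replicate,
                                   double fill) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n = coords.nrow();
  NumericVector out(n);
  for (int q = 0; q < n; ++q) {
    double x = coords(q, 0), y = coords(q, 1), z = coords(q, 2);
    if (!edge_replicate &&
        (x < -0.5 || y < -0.5 || z < -0.5 ||
         x > nx - 0.5 || y > ny - 0.5 || z > nz - 0.5)) {
      out[q] = fill;
      continue;
    }
    if (edge_replicate) {
      x = std::min(std::max(x, 0.0), (double)(nx - 1));
      y = std::min(std::max(y, 0.0), (double)(ny - 1));
      z = std::min(std::max(z, 0.0), (double)(nz - 1));
    }
    int ix = (int)std::floor(x), iy = (int)std::floor(y), iz = (int)std::floor(z);
    double fx = x - ix, fy = y - iy, fz = z - iz;
    double acc = 0.0;
    for (int c = 0; c < 2; ++c) {
      int kz = iz + c;
      double wz = c ? fz : 1.0 - fz;
      if (wz == 0.0) continue;
      for (int b = 0; b < 2; ++b) {
        int ky = iy + b;
        double wyz = (b ? fy : 1.0 - fy) * wz;
        if (wyz == 0.0) continue;
        for (int a = 0; a < 2; ++a) {
          int kx = ix + a;
          double w = (a ? fx : 1.0 - fx) * wyz;
          if (w == 0.0) continue;
          double v;
          if (kx < 0 || ky < 0 || kz < 0 || kx >= nx || ky >= ny || kz >= nz) {
            if (edge_replicate) {
              int cx = std::min(std::max(kx, 0), nx - 1);
              int cy = std::min(std::max(ky, 0), ny - 1);
              int cz = std::min(std::max(kz, 0), nz - 1);
              v = vol[cx + (size_t)nx * (cy + (size_t)ny * cz)];
            } else {
              v = fill;
            }
          } else {
            v = vol[kx + (size_t)nx * (ky + (size_t)ny * kz)];
          }
          acc += w * v;
        }
      }
    }
    out[q] = acc;
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_sample_nearest(IntegerVector vol, IntegerVector dims,
                                 NumericMatrix coords, int fill) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n = coords.nrow();
  IntegerVector out(n);
  for (int q = 0; q < n; ++q) {
    int ix = (int)std::lround(coords(q, 0));
    int iy = (int)std::lround(coords(q, 1));
    int iz = (int)std::lround(coords(q, 2));
    if (ix < 0 || iy < 0 || iz < 0 || ix >= nx || iy >= ny || iz >= nz)
      out[q] = fill;
    else
      out[q] = vol[ix + (size_t)nx * (iy + (size_t)ny * iz)];
  }
  return out;
}

// One-hot trilinear label interpolation with argmax decoding.
// Out-of-bounds corners contribute their weight to background (0).
// Ties go to the lowest label id.
// [[Rcpp::export]]
IntegerVector cpp_resample_labels_onehot(IntegerVector vol, IntegerVector dims,
                                         NumericMatrix coords) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n = coords.nrow();
  IntegerVector out(n);
  int labs[8];
  double wts[8];
  for (int q = 0; q < n; ++q) {
    double x = coords(q, 0), y = coords(q, 1), z = coords(q, 2);
    int ix = (int)std::floor(x), iy = (int)std::floor(y), iz = (int)std::floor(z);
    double fx = x - ix, fy = y - iy, fz = z - iz;
    int m = 0;
    for (int c = 0; c < 2; ++c) {
      int kz = iz + c;
      double wz = c ? fz : 1.0 - fz;
      for (int b = 0; b < 2; ++b) {
        int ky = iy + b;
        double wyz = (b ? fy : 1.0 - fy) * wz;
        for (int a = 0; a < 2; ++a) {
          int kx = ix + a;
          double w = (a ? fx : 1.0 - fx) * wyz;
          if (w <= 0.0) continue;
          int lab = 0;
          if (kx >= 0 && ky >= 0 && kz >= 0 && kx < nx && ky < ny && kz < nz)
            lab = vol[kx + (size_t)nx * (ky + (size_t)ny * kz)];
          int slot = -1;
          for (int t = 0; t < m; ++t)
            if (labs[t] == lab) { slot = t; break; }
          if (slot < 0) { slot = m++; labs[slot] = lab; wts[slot] = 0.0; }
          wts[slot] += w;
        }
      }
    }
    int best = 0; double bw = -1.0;
    for (int t = 0; t < m; ++t) {
      if (wts[t] > bw + 1e-12 ||
          (std::fabs(wts[t] - bw) <= 1e-12 && labs[t] < best)) {
        bw = wts[t]; best = labs[t];
      }
    }
    out[q] = best;
  }
  return out;
}
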