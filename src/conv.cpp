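#include <Rcpp.h>
using namespace Rcpp;

// im2col / col2im for 3D convolution with odd kernel k, zero padding (k-1)/2,
// stride 1. Activations are R arrays dim c(nx, ny, nz, C) (voxel fastest).
// The col matrix is V x (k^3 * C) with V = nx*ny*nz; column index
// r = t + k^3 * c where t enumerates kernel offsets x-fastest. A weight
// matrix of shape (k^3*C_in, C_out) then gives the convolution output as
// col %*% W, reshapeable to c(nx, ny, nz, C_out).

// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector x, IntegerVector dims, int k) {
  int nx = dims[0], ny = dims[1], nz = dims[2], C = dims[3];
  int pad = (k - 1) / 2, k3 = k * k * k;
  size_t V = (size_t)nx * ny * nz;
  // allocMatrix avoids the zero-fill of the NumericMatrix(n, m) constructor;
  // every entry (including padding) is written below
  NumericMatrix col(Rf_allocMatrix(REALSXP, V, (size_t)k3 * C));
  for (int c = 0; c < C; ++c) {
    const double* xc = &x[(size_t)c * V];
    for (int dz = -pad; dz <= pad; ++dz)
      for (int dy = -pad; dy <= pad; ++dy)
        for (int dx = -pad; dx <= pad; ++dx) {
          int t = (dx + pad) + k * ((dy + pad) + k * (dz + pad));
          double* out = &col(0, t + k3 * c);
          for (int z = 0; z < nz; ++z) {
            int zz = z + dz;
            bool zok = (zz >= 0 && zz < nz);
            for (int y = 0; y < ny; ++y) {
              int yy = y + dy;
              bool yok = zok && (yy >= 0 && yy < ny);
              size_t orow = (size_t)nx * (y + (size_t)ny * z);
              if (!yok) {
                for (int xi = 0; xi < nx; ++xi) out[orow + xi] = 0.0;
                continue;
              }
              size_t irow = (size_t)nx * (yy + (size_t)ny * zz);
              int x0 = std::max(0, -dx), x1 = std::min(nx, nx - dx);
              for (int xi = 0; xi < x0; ++xi) out[orow + xi] = 0.0;
              for (int xi = x0; xi < x1; ++xi) out[orow + xi] = xc[irow + xi + dx];
              for (int xi = x1; xi < nx; ++xi) out[orow + xi] = 0.0;
            }
          }
        }
  }
  return col;
}

// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix dcol, IntegerVector dims, int k) {
  int nx = dims[0], ny = dims[1], nz = dims[2], C = dims[3];
  int pad = (k - 1) / 2, k3 = k * k * k;
  size_t V = (size_t)nx * ny * nz;
  NumericVector dx_out((size_t)V * C);
  for (int c = 0; c < C; ++c) {
    double* xc = &dx_out[(size_t)c * V];
    for (int dz = -pad; dz <= pad; ++dz)
      for (int dy = -pad; dy <= pad; ++dy)
        for (int dx = -pad; dx <= pad; ++dx) {
          int t = (dx + pad) + k * ((dy + pad) + k * (dz + pad));
          const double* in = &dcol(0, t + k3 * c);
          for (int z = 0; z < nz; ++z) {
            int zz = z + dz;
            if (zz < 0 || zz >= nz) continue;
            for (int y = 0; y < ny; ++y) {
              int yy = y + dy;
              if (yy < 0 || yy >= ny) continue;
              size_t orow = (size_t)nx * (y + (size_t)ny * z);
              size_t irow = (size_t)nx * (yy + (size_t)ny * zz);
              int x0 = std::max(0, -dx), x1 = std::min(nx, nx - dx);
              for (int xi = x0; xi < x1; ++xi)
                xc[irow + xi + dx] += in[orow + xi];
            }
          }
        }
  }
  dx_out.attr("dim") = dims;
  return dx_out;
}

// [[Rcpp::export]]
NumericVector cpp_lrelu_fwd(NumericVector x, double slope) {
  NumericVector y(Rf_allocVector(REALSXP, x.size()));
  for (R_xlen_t i = 0; i < x.size(); ++i)
    y[i] = x[i] > 0 ? x[i] : slope * x[i];
  y.attr("dim") = x.attr("dim");
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_lrelu_bwd(NumericVector dy, NumericVector y, double slope) {
  NumericVector g(Rf_allocVector(REALSXP, dy.size()));
  for (R_xlen_t i = 0; i < dy.size(); ++i)
    g[i] = y[i] > 0 ? dy[i] : slope * dy[i];
  g.attr("dim") = dy.attr("dim");
  return g;
}

// 2x2x2 max pooling (spatial dims must be even). Returns pooled array and
// 1-based argmax indices into the input for the backward pass.
// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericVector x, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2], C = dims[3];
  int mx = nx / 2, my = ny / 2, mz = nz / 2;
  size_t Vo = (size_t)mx * my * mz * C;
  NumericVector y(Vo);
  IntegerVector arg(Vo);
  for (int c = 0; c < C; ++c)
    for (int z = 0; z < mz; ++z)
      for (int yy = 0; yy < my; ++yy)
        for (int xx = 0; xx < mx; ++xx) {
          double best = R_NegInf;
          size_t besti = 0;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dx = 0; dx < 2; ++dx) {
                size_t idx = (2 * xx + dx) +
                  (size_t)nx * ((2 * yy + dy) +
                  (size_t)ny * ((2 * z + dz) + (size_t)nz * c));
                if (x[idx] > best) { best = x[idx]; besti = idx; }
              }
          size_t o = xx + (size_t)mx * (yy + (size_t)my * (z + (size_t)mz * c));
          y[o] = best;
          arg[o] = (int)(besti + 1);
        }
  y.attr("dim") = IntegerVector::create(mx, my, mz, C);
  return List::create(_["y"] = y, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(NumericVector dy, IntegerVector argmax,
                              IntegerVector in_dims) {
  size_t n = (size_t)in_dims[0] * in_dims[1] * in_dims[2] * in_dims[3];
  NumericVector dx_out(n);
  for (R_xlen_t i = 0; i < dy.size(); ++i)
    dx_out[argmax[i] - 1] += dy[i];
  dx_out.attr("dim") = in_dims;
  return dx_out;
}
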