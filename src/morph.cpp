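#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// 3D binary morphology and connected components on column-major grids.
// connectivity: 6 (faces), 18 (faces+edges) or 26 (full neighborhood).

static int neighbor_offsets(int connectivity, int nbr[26][3]) {
  int m = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (manh == 0) continue;
        if (connectivity == 6 && manh > 1) continue;
        if (connectivity == 18 && manh > 2) continue;
        nbr[m][0] = dx; nbr[m][1] = dy; nbr[m][2] = dz; ++m;
      }
  return m;
}

// [[Rcpp::export]]
LogicalVector cpp_binary_dilate(LogicalVector mask, IntegerVector dims,
                                int iterations, int connectivity) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int nbr[26][3];
  int m = neighbor_offsets(connectivity, nbr);
  std::vector<char> cur(mask.begin(), mask.end()), nxt;
  for (int it = 0; it < iterations; ++it) {
    nxt = cur;
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          size_t idx = x + (size_t)nx * (y + (size_t)ny * z);
          if (cur[idx]) continue;
          for (int t = 0; t < m; ++t) {
            int xx = x + nbr[t][0], yy = y + nbr[t][1], zz = z + nbr[t][2];
            if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
              continue;
            if (cur[xx + (size_t)nx * (yy + (size_t)ny * zz)]) {
              nxt[idx] = 1;
              break;
            }
          }
        }
    cur.swap(nxt);
  }
  return LogicalVector(cur.begin(), cur.end());
}

// [[Rcpp::export]]
LogicalVector cpp_binary_erode(LogicalVector mask, IntegerVector dims,
                               int iterations, int connectivity) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int nbr[26][3];
  int m = neighbor_offsets(connectivity, nbr);
  std::vector<char> cur(mask.begin(), mask.end()), nxt;
  for (int it = 0; it < iterations; ++it) {
    nxt = cur;
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          size_t idx = x + (size_t)nx * (y + (size_t)ny * z);
          if (!cur[idx]) continue;
          for (int t = 0; t < m; ++t) {
            int xx = x + nbr[t][0], yy = y + nbr[t][1], zz = z + nbr[t][2];
            bool off = (xx < 0 || yy < 0 || zz < 0 ||
                        xx >= nx || yy >= ny || zz >= nz);
            if (off || !cur[xx + (size_t)nx * (yy + (size_t)ny * zz)]) {
              nxt[idx] = 0;
              break;
            }
          }
        }
    cur.swap(nxt);
  }
  return LogicalVector(cur.begin(), cur.end());
}

// Fill interior holes: background components not reachable from the volume
// border (6-connected flood) become foreground.
// [[Rcpp::export]]
LogicalVector cpp_fill_holes(LogicalVector mask, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t n = (size_t)nx * ny * nz;
  std::vector<char> outside(n, 0);
  std::queue<size_t> qu;
  auto idx3 = [&](int x, int y, int z) {
    return x + (size_t)nx * (y + (size_t)ny * z);
  };
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        if (x > 0 && x < nx - 1 && y > 0 && y < ny - 1 && z > 0 && z < nz - 1)
          continue;
        size_t idx = idx3(x, y, z);
        if (!mask[idx] && !outside[idx]) { outside[idx] = 1; qu.push(idx); }
      }
  const int off[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  while (!qu.empty()) {
    size_t idx = qu.front(); qu.pop();
    int x = idx % nx, y = (idx / nx) % ny, z = idx / ((size_t)nx * ny);
    for (int t = 0; t < 6; ++t) {
      int xx = x + off[t][0], yy = y + off[t][1], zz = z + off[t][2];
      if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
        continue;
      size_t jdx = idx3(xx, yy, zz);
      if (!mask[jdx] && !outside[jdx]) { outside[jdx] = 1; qu.push(jdx); }
    }
  }
  LogicalVector out(n);
  for (size_t i = 0; i < n; ++i) out[i] = mask[i] || !outside[i];
  return out;
}

// Label connected components of a binary mask; returns an integer grid with
// components numbered 1..k in decreasing-size-agnostic scan order, plus sizes.
// [[Rcpp::export]]
List cpp_connected_components(LogicalVector mask, IntegerVector dims,
                              int connectivity) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t n = (size_t)nx * ny * nz;
  int nbr[26][3];
  int m = neighbor_offsets(connectivity, nbr);
  IntegerVector comp(n, 0);
  std::vector<double> sizes;
  std::queue<size_t> qu;
  int k = 0;
  for (size_t s = 0; s < n; ++s) {
    if (!mask[s] || comp[s]) continue;
    ++k;
    double sz = 0;
    comp[s] = k;
    qu.push(s);
    while (!qu.empty()) {
      size_t idx = qu.front(); qu.pop();
      ++sz;
      int x = idx % nx, y = (idx / nx) % ny, z = idx / ((size_t)nx * ny);
      for (int t = 0; t < m; ++t) {
        int xx = x + nbr[t][0], yy = y + nbr[t][1], zz = z + nbr[t][2];
        if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
          continue;
        size_t jdx = xx + (size_t)nx * (yy + (size_t)ny * zz);
        if (mask[jdx] && !comp[jdx]) { comp[jdx] = k; qu.push(jdx); }
      }
    }
    sizes.push_back(sz);
  }
  comp.attr("dim") = dims;
  return List::create(_["labels"] = comp, _["sizes"] = wrap(sizes));
}

// Surface voxels: foreground voxels with at least one face-adjacent background
// neighbor (voxels on the volume border count as adjacent to background).
// Returns 0-based (x, y, z) indices.
// [[Rcpp::export]]
IntegerMatrix cpp_surface_voxels(LogicalVector mask, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  const int off[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  std::vector<int> xs, ys, zs;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        if (!mask[x + (size_t)nx * (y + (size_t)ny * z)]) continue;
        bool surf = false;
        for (int t = 0; t < 6 && !surf; ++t) {
          int xx = x + off[t][0], yy = y + off[t][1], zz = z + off[t][2];
          if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
            surf = true;
          else if (!mask[xx + (size_t)nx * (yy + (size_t)ny * zz)])
            surf = true;
        }
        if (surf) { xs.push_back(x); ys.push_back(y); zs.push_back(z); }
      }
  IntegerMatrix out(xs.size(), 3);
  for (size_t i = 0; i < xs.size(); ++i) {
    out(i, 0) = xs[i]; out(i, 1) = ys[i]; out(i, 2) = zs[i];
  }
  return out;
}

// Sum over points in A of the Euclidean distance to the nearest point in B.
// Points are world-coordinate rows (mm).
// [[Rcpp::export]]
double cpp_directed_nn_distance_sum(NumericMatrix A, NumericMatrix B) {
  int na = A.nrow(), nb = B.nrow();
  double total = 0.0;
  for (int i = 0; i < na; ++i) {
    double best = R_PosInf;
    double ax = A(i, 0), ay = A(i, 1), az = A(i, 2);
    for (int j = 0; j < nb; ++j) {
      double dx = ax - B(j, 0), dy = ay - B(j, 1), dz = az - B(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    total += std::sqrt(best);
  }
  return total;
}
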