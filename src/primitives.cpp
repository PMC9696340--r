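#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <limits>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Exact Euclidean distance transform (squared-distance lower-envelope method,
// separable in the three axes). Distances are in voxel units on an isotropic
// grid. Foreground voxels (mask TRUE) receive the distance to the nearest
// background voxel; background voxels receive 0.
// ---------------------------------------------------------------------------

static void dt1d(std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z, int n) {
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export(name = ".edt3d")]]
NumericVector edt3d(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  // large finite sentinel: true infinity breaks the parabola-envelope
  // arithmetic (inf - inf); 1e30 dominates any realizable squared distance
  const double BIG = 1e30;
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] ? BIG : 0.0;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // x direction
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx;
      for (int i = 0; i < nx; ++i) f[i] = out[base + i];
      dt1d(f, d, v, z, nx);
      for (int i = 0; i < nx; ++i) out[base + i] = d[i];
    }
  // y direction
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = (R_xlen_t)k * nx * ny + i;
      for (int j = 0; j < ny; ++j) f[j] = out[base + (R_xlen_t)j * nx];
      dt1d(f, d, v, z, ny);
      for (int j = 0; j < ny; ++j) out[base + (R_xlen_t)j * nx] = d[j];
    }
  // z direction
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = (R_xlen_t)j * nx + i;
      for (int k = 0; k < nz; ++k) f[k] = out[base + (R_xlen_t)k * nx * ny];
      dt1d(f, d, v, z, nz);
      for (int k = 0; k < nz; ++k) out[base + (R_xlen_t)k * nx * ny] = d[k];
    }
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = out[i] >= BIG / 2 ? R_PosInf : std::sqrt(out[i]);
  return out;
}

// ---------------------------------------------------------------------------
// Brute-force exact k-nearest-neighbour prediction with the documented
// deterministic tie-breaks: neighbours are the k smallest by (squared
// distance, training index); a tied vote falls back to the label of the
// single nearest neighbour.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".knn_predict")]]
IntegerVector knn_predict(NumericMatrix train, IntegerVector labels,
                          NumericMatrix probes, int k) {
  const int ntr = train.nrow(), d = train.ncol(), np = probes.nrow();
  if (k < 1 || k > ntr) stop("k must be in [1, nrow(train)]");
  IntegerVector out(np);
  std::vector<double> tr((size_t)ntr * d);
  for (int j = 0; j < d; ++j)
    for (int i = 0; i < ntr; ++i) tr[(size_t)i * d + j] = train(i, j);
  std::vector<double> bestd(k);
  std::vector<int> besti(k);
  std::vector<double> p(d);
  for (int q = 0; q < np; ++q) {
    for (int j = 0; j < d; ++j) p[j] = probes(q, j);
    int filled = 0;
    double worst = std::numeric_limits<double>::infinity();
    for (int i = 0; i < ntr; ++i) {
      const double* t = &tr[(size_t)i * d];
      double dist = 0.0;
      for (int j = 0; j < d; ++j) {
        double df = p[j] - t[j];
        dist += df * df;
      }
      if (filled == k && dist >= worst) continue;
      // insert keeping ascending (dist, index) order; ascending scan over i
      // means strict '<' preserves earlier indices on distance ties
      int pos = filled < k ? filled : k - 1;
      while (pos > 0 && bestd[pos - 1] > dist) {
        bestd[pos] = bestd[pos - 1];
        besti[pos] = besti[pos - 1];
        --pos;
      }
      bestd[pos] = dist;
      besti[pos] = i;
      if (filled < k) ++filled;
      if (filled == k) worst = bestd[k - 1];
    }
    int votes = 0;
    for (int j = 0; j < filled; ++j) votes += labels[besti[j]];
    int lab;
    if (2 * votes > filled) lab = 1;
    else if (2 * votes < filled) lab = 0;
    else lab = labels[besti[0]];
    out[q] = lab;
    if (q % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// ---------------------------------------------------------------------------
// 3D bilateral filter: Gaussian spatial kernel (sigma in voxels, window
// truncated at 2.5 sigma, radius capped at 6) times Gaussian range kernel
// (sigma in gray units). Borders use the truncated window.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".bilateral3d")]]
NumericVector bilateral3d(NumericVector vol, IntegerVector dim,
                          double sigma_spatial, double sigma_range) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  int r = (int)std::ceil(2.5 * sigma_spatial);
  if (r < 1) r = 1;
  if (r > 6) r = 6;
  const int w = 2 * r + 1;
  std::vector<double> sw((size_t)w * w * w);
  for (int dz = -r; dz <= r; ++dz)
    for (int dy = -r; dy <= r; ++dy)
      for (int dx = -r; dx <= r; ++dx)
        sw[(size_t)(dz + r) * w * w + (size_t)(dy + r) * w + (dx + r)] =
          std::exp(-0.5 * (dx * dx + dy * dy + dz * dz) /
                   (sigma_spatial * sigma_spatial));
  const double inv2sr2 = 0.5 / (sigma_range * sigma_range);
  NumericVector out((R_xlen_t)nx * ny * nz);
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        R_xlen_t idx = (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx + i;
        double c = vol[idx], num = 0.0, den = 0.0;
        int z0 = std::max(0, k - r), z1 = std::min(nz - 1, k + r);
        int y0 = std::max(0, j - r), y1 = std::min(ny - 1, j + r);
        int x0 = std::max(0, i - r), x1 = std::min(nx - 1, i + r);
        for (int kk = z0; kk <= z1; ++kk)
          for (int jj = y0; jj <= y1; ++jj) {
            R_xlen_t nbase = (R_xlen_t)kk * nx * ny + (R_xlen_t)jj * nx;
            const double* swrow = &sw[(size_t)(kk - k + r) * w * w +
                                      (size_t)(jj - j + r) * w + (x0 - i + r)];
            for (int ii = x0; ii <= x1; ++ii) {
              double v = vol[nbase + ii];
              double dv = v - c;
              double wgt = swrow[ii - x0] * std::exp(-dv * dv * inv2sr2);
              num += wgt * v;
              den += wgt;
            }
          }
        out[idx] = num / den;
      }
    }
    Rcpp::checkUserInterrupt();
  }
  return out;
}

// ---------------------------------------------------------------------------
// 6-connected binary erosion (voxels outside the grid count as background).
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".erode6")]]
LogicalVector erode6(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  LogicalVector out((R_xlen_t)nx * ny * nz);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t idx = (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx + i;
        bool keep = mask[idx];
        if (keep) {
          keep = i > 0 && mask[idx - 1] && i < nx - 1 && mask[idx + 1] &&
                 j > 0 && mask[idx - nx] && j < ny - 1 && mask[idx + nx] &&
                 k > 0 && mask[idx - (R_xlen_t)nx * ny] &&
                 k < nz - 1 && mask[idx + (R_xlen_t)nx * ny];
        }
        out[idx] = keep;
      }
  return out;
}

// ---------------------------------------------------------------------------
// Connected-component labelling of a binary volume, 26- or 6-connectivity,
// iterative flood fill. Labels are 1..n in scan order; background is 0.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".label_components")]]
IntegerVector label_components(LogicalVector mask, IntegerVector dim,
                               int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n);
  std::vector<int> offs_dx, offs_dy, offs_dz;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh != 1) continue;
        offs_dx.push_back(dx); offs_dy.push_back(dy); offs_dz.push_back(dz);
      }
  int current = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++current;
    stack.push_back(s);
    lab[s] = current;
    while (!stack.empty()) {
      R_xlen_t idx = stack.back();
      stack.pop_back();
      int i = (int)(idx % nx);
      int j = (int)((idx / nx) % ny);
      int k = (int)(idx / ((R_xlen_t)nx * ny));
      for (size_t o = 0; o < offs_dx.size(); ++o) {
        int ii = i + offs_dx[o], jj = j + offs_dy[o], kk = k + offs_dz[o];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
          continue;
        R_xlen_t nidx = (R_xlen_t)kk * nx * ny + (R_xlen_t)jj * nx + ii;
        if (mask[nidx] && lab[nidx] == 0) {
          lab[nidx] = current;
          stack.push_back(nidx);
        }
      }
    }
    Rcpp::checkUserInterrupt();
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Trilinear resampling. Output voxel (i,j,k) (0-based) samples the input at
// continuous 0-based coordinate origin + index*step per axis; coordinates
// outside the input grid return `fill`.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".resample_trilinear")]]
NumericVector resample_trilinear(NumericVector vol, IntegerVector dim,
                                 IntegerVector out_dim, NumericVector origin,
                                 NumericVector step, double fill) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int ox = out_dim[0], oy = out_dim[1], oz = out_dim[2];
  NumericVector out((R_xlen_t)ox * oy * oz);
  for (int k = 0; k < oz; ++k) {
    double zc = origin[2] + k * step[2];
    int z0 = (int)std::floor(zc);
    double fz = zc - z0;
    for (int j = 0; j < oy; ++j) {
      double yc = origin[1] + j * step[1];
      int y0 = (int)std::floor(yc);
      double fy = yc - y0;
      for (int i = 0; i < ox; ++i) {
        double xc = origin[0] + i * step[0];
        int x0 = (int)std::floor(xc);
        double fx = xc - x0;
        R_xlen_t oidx = (R_xlen_t)k * ox * oy + (R_xlen_t)j * ox + i;
        if (xc < 0 || xc > nx - 1 || yc < 0 || yc > ny - 1 ||
            zc < 0 || zc > nz - 1) {
          out[oidx] = fill;
          continue;
        }
        int x1 = std::min(x0 + 1, nx - 1);
        int y1 = std::min(y0 + 1, ny - 1);
        int z1 = std::min(z0 + 1, nz - 1);
        R_xlen_t p000 = (R_xlen_t)z0 * nx * ny + (R_xlen_t)y0 * nx + x0;
        R_xlen_t p100 = (R_xlen_t)z0 * nx * ny + (R_xlen_t)y0 * nx + x1;
        R_xlen_t p010 = (R_xlen_t)z0 * nx * ny + (R_xlen_t)y1 * nx + x0;
        R_xlen_t p110 = (R_xlen_t)z0 * nx * ny + (R_xlen_t)y1 * nx + x1;
        R_xlen_t p001 = (R_xlen_t)z1 * nx * ny + (R_xlen_t)y0 * nx + x0;
        R_xlen_t p101 = (R_xlen_t)z1 * nx * ny + (R_xlen_t)y0 * nx + x1;
        R_xlen_t p011 = (R_xlen_t)z1 * nx * ny + (R_xlen_t)y1 * nx + x0;
        R_xlen_t p111 = (R_xlen_t)z1 * nx * ny + (R_xlen_t)y1 * nx + x1;
        double c00 = vol[p000] * (1 - fx) + vol[p100] * fx;
        double c10 = vol[p010] * (1 - fx) + vol[p110] * fx;
        double c01 = vol[p001] * (1 - fx) + vol[p101] * fx;
        double c11 = vol[p011] * (1 - fx) + vol[p111] * fx;
        double c0 = c00 * (1 - fy) + c10 * fy;
        double c1 = c01 * (1 - fy) + c11 * fy;
        out[oidx] = c0 * (1 - fz) + c1 * fz;
      }
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Background reachable from the grid border through 6-connected non-mask
// voxels; used for hole filling (holes = !mask & !reachable).
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".flood_background")]]
LogicalVector flood_background(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector reach(n);
  std::vector<R_xlen_t> stack;
  auto push = [&](int i, int j, int k) {
    R_xlen_t idx = (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx + i;
    if (!mask[idx] && !reach[idx]) {
      reach[idx] = TRUE;
      stack.push_back(idx);
    }
  };
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i)
        if (i == 0 || i == nx - 1 || j == 0 || j == ny - 1 ||
            k == 0 || k == nz - 1)
          push(i, j, k);
  while (!stack.empty()) {
    R_xlen_t idx = stack.back();
    stack.pop_back();
    int i = (int)(idx % nx);
    int j = (int)((idx / nx) % ny);
    int k = (int)(idx / ((R_xlen_t)nx * ny));
    if (i > 0) push(i - 1, j, k);
    if (i < nx - 1) push(i + 1, j, k);
    if (j > 0) push(i, j - 1, k);
    if (j < ny - 1) push(i, j + 1, k);
    if (k > 0) push(i, j, k - 1);
    if (k < nz - 1) push(i, j, k + 1);
  }
  return reach;
}
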