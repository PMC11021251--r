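#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Linear index helpers: R arrays are column-major, dim = (nx, ny, nz), x fastest.
static inline R_xlen_t lidx(int i, int j, int k, int nx, int ny) {
  return (R_xlen_t)i + (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * (R_xlen_t)k);
}

// ---------------------------------------------------------------------------
// Separable 1D convolution along one axis with replicate (nearest) borders.
// axis: 0 = x, 1 = y, 2 = z. Kernel length must be odd; centre at (len-1)/2.
// [[Rcpp::export(name = ".cpp_conv1d")]]
NumericVector cpp_conv1d(NumericVector data, IntegerVector dim,
                         NumericVector kernel, int axis) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int klen = kernel.size(), kh = (klen - 1) / 2;
  NumericVector out(data.size());
  const int n[3] = {nx, ny, nz};
  const int alen = n[axis];

  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double acc = 0.0;
        int pos[3] = {i, j, k};
        for (int t = -kh; t <= kh; ++t) {
          int q = pos[axis] + t;
          if (q < 0) q = 0;
          if (q >= alen) q = alen - 1;
          int p[3] = {i, j, k};
          p[axis] = q;
          acc += kernel[t + kh] * data[lidx(p[0], p[1], p[2], nx, ny)];
        }
        out[lidx(i, j, k, nx, ny)] = acc;
      }
  return out;
}

// ---------------------------------------------------------------------------
// Binary dilation by an explicit offset set (rows of `off`: i, j, k).
// Out-of-grid contributions are dropped (clipped at the border).
// [[Rcpp::export(name = ".cpp_dilate")]]
LogicalVector cpp_dilate(LogicalVector mask, IntegerVector dim, IntegerMatrix off) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  LogicalVector out(mask.size(), false);
  const int ns = off.nrow();
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        if (!mask[lidx(i, j, k, nx, ny)]) continue;
        for (int s = 0; s < ns; ++s) {
          int ii = i + off(s, 0), jj = j + off(s, 1), kk = k + off(s, 2);
          if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
          out[lidx(ii, jj, kk, nx, ny)] = true;
        }
      }
  return out;
}

// Binary erosion; voxels outside the grid count as background, so objects
// touching the border are eroded there (the usual finite-grid convention).
// [[Rcpp::export(name = ".cpp_erode")]]
LogicalVector cpp_erode(LogicalVector mask, IntegerVector dim, IntegerMatrix off) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  LogicalVector out(mask.size(), false);
  const int ns = off.nrow();
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        if (!mask[lidx(i, j, k, nx, ny)]) continue;
        bool keep = true;
        for (int s = 0; s < ns; ++s) {
          int ii = i + off(s, 0), jj = j + off(s, 1), kk = k + off(s, 2);
          if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz ||
              !mask[lidx(ii, jj, kk, nx, ny)]) {
            keep = false;
            break;
          }
        }
        if (keep) out[lidx(i, j, k, nx, ny)] = true;
      }
  return out;
}

// ---------------------------------------------------------------------------
// Connected components by breadth-first search in voxel scan order, so the
// component containing the first foreground voxel in scan order gets code 1.
// connectivity: 6 or 26.
// [[Rcpp::export(name = ".cpp_components")]]
IntegerVector cpp_components(LogicalVector mask, IntegerVector dim, int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  IntegerVector lab(mask.size(), 0);
  std::vector<int> di, dj, dk;
  for (int c = -1; c <= 1; ++c)
    for (int b = -1; b <= 1; ++b)
      for (int a = -1; a <= 1; ++a) {
        if (a == 0 && b == 0 && c == 0) continue;
        if (connectivity == 6 && std::abs(a) + std::abs(b) + std::abs(c) != 1) continue;
        di.push_back(a); dj.push_back(b); dk.push_back(c);
      }
  const int nn = (int)di.size();
  int ncomp = 0;
  std::vector<int> stack;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t v = lidx(i, j, k, nx, ny);
        if (!mask[v] || lab[v]) continue;
        ++ncomp;
        lab[v] = ncomp;
        stack.clear();
        stack.push_back((int)v);
        while (!stack.empty()) {
          int cur = stack.back();
          stack.pop_back();
          int ck = cur / (nx * ny), rem = cur % (nx * ny);
          int cj = rem / nx, ci = rem % nx;
          for (int s = 0; s < nn; ++s) {
            int ii = ci + di[s], jj = cj + dj[s], kk = ck + dk[s];
            if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
            R_xlen_t w = lidx(ii, jj, kk, nx, ny);
            if (mask[w] && !lab[w]) {
              lab[w] = ncomp;
              stack.push_back((int)w);
            }
          }
        }
      }
  return lab;
}

// ---------------------------------------------------------------------------
// Exact Chebyshev (chessboard) distance transform via two-pass chamfer with
// unit weights over the 26-neighbourhood (exact for the L-infinity metric).
// Empty mask -> all NA_integer_.
// [[Rcpp::export(name = ".cpp_chessboard_dt")]]
IntegerVector cpp_chessboard_dt(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int INF = std::numeric_limits<int>::max() / 4;
  std::vector<int> d(mask.size());
  bool any = false;
  for (R_xlen_t v = 0; v < mask.size(); ++v) {
    d[v] = mask[v] ? 0 : INF;
    if (mask[v]) any = true;
  }
  IntegerVector out(mask.size());
  if (!any) {
    std::fill(out.begin(), out.end(), NA_INTEGER);
    return out;
  }
  // forward pass
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t v = lidx(i, j, k, nx, ny);
        int best = d[v];
        for (int c = -1; c <= 0; ++c)
          for (int b = -1; b <= 1; ++b)
            for (int a = -1; a <= 1; ++a) {
              if (c == 0 && (b > 0 || (b == 0 && a >= 0))) continue;
              int ii = i + a, jj = j + b, kk = k + c;
              if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
              int cand = d[lidx(ii, jj, kk, nx, ny)] + 1;
              if (cand < best) best = cand;
            }
        d[v] = best;
      }
  // backward pass
  for (int k = nz - 1; k >= 0; --k)
    for (int j = ny - 1; j >= 0; --j)
      for (int i = nx - 1; i >= 0; --i) {
        R_xlen_t v = lidx(i, j, k, nx, ny);
        int best = d[v];
        for (int c = 0; c <= 1; ++c)
          for (int b = -1; b <= 1; ++b)
            for (int a = -1; a <= 1; ++a) {
              if (c == 0 && (b < 0 || (b == 0 && a <= 0))) continue;
              int ii = i + a, jj = j + b, kk = k + c;
              if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
              int cand = d[lidx(ii, jj, kk, nx, ny)] + 1;
              if (cand < best) best = cand;
            }
        d[v] = best;
      }
  for (R_xlen_t v = 0; v < mask.size(); ++v) out[v] = d[v];
  return out;
}

// ---------------------------------------------------------------------------
// Exact Euclidean distance transform (Felzenszwalb & Huttenlocher separable
// squared-distance transform), anisotropic spacing in mm. Empty mask -> NA.
static void edt_1d(std::vector<double> &f, std::vector<double> &d, double w2) {
  const int n = (int)f.size();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int kk = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      int p = v[kk];
      s = ((f[q] + w2 * q * q) - (f[p] + w2 * p * p)) / (2.0 * w2 * (q - p));
      if (s <= z[kk]) { --kk; } else break;
    }
    ++kk;
    v[kk] = q;
    z[kk] = s;
    z[kk + 1] = std::numeric_limits<double>::infinity();
  }
  kk = 0;
  for (int q = 0; q < n; ++q) {
    while (z[kk + 1] < q) ++kk;
    int p = v[kk];
    d[q] = w2 * (q - p) * (q - p) + f[p];
  }
}

// [[Rcpp::export(name = ".cpp_euclidean_dt")]]
NumericVector cpp_euclidean_dt(LogicalVector mask, IntegerVector dim,
                               NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  // large finite sentinel: IEEE infinities would make the parabola
  // intersection abscissae NaN (inf - inf) and corrupt the lower envelope
  const double INF = 1e20;
  std::vector<double> g(mask.size());
  bool any = false;
  for (R_xlen_t v = 0; v < mask.size(); ++v) {
    g[v] = mask[v] ? 0.0 : INF;
    if (mask[v]) any = true;
  }
  NumericVector out(mask.size());
  if (!any) {
    std::fill(out.begin(), out.end(), NA_REAL);
    return out;
  }
  // x axis
  {
    std::vector<double> f(nx), d(nx);
    double w2 = spacing[0] * spacing[0];
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j) {
        for (int i = 0; i < nx; ++i) f[i] = g[lidx(i, j, k, nx, ny)];
        edt_1d(f, d, w2);
        for (int i = 0; i < nx; ++i) g[lidx(i, j, k, nx, ny)] = d[i];
      }
  }
  // y axis
  {
    std::vector<double> f(ny), d(ny);
    double w2 = spacing[1] * spacing[1];
    for (int k = 0; k < nz; ++k)
      for (int i = 0; i < nx; ++i) {
        for (int j = 0; j < ny; ++j) f[j] = g[lidx(i, j, k, nx, ny)];
        edt_1d(f, d, w2);
        for (int j = 0; j < ny; ++j) g[lidx(i, j, k, nx, ny)] = d[j];
      }
  }
  // z axis
  {
    std::vector<double> f(nz), d(nz);
    double w2 = spacing[2] * spacing[2];
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        for (int k = 0; k < nz; ++k) f[k] = g[lidx(i, j, k, nx, ny)];
        edt_1d(f, d, w2);
        for (int k = 0; k < nz; ++k) g[lidx(i, j, k, nx, ny)] = d[k];
      }
  }
  for (R_xlen_t v = 0; v < mask.size(); ++v) out[v] = std::sqrt(g[v]);
  return out;
}

// ---------------------------------------------------------------------------
// Resampling to a new grid. Voxel centre of index i (0-based) sits at world
// position (i + 0.5) * spacing; both grids share the world origin at the
// corner of voxel (0,0,0). method: 0 = trilinear, 1 = nearest neighbour.
// [[Rcpp::export(name = ".cpp_resample")]]
NumericVector cpp_resample(NumericVector data, IntegerVector dim,
                           NumericVector in_sp, IntegerVector odim,
                           NumericVector out_sp, int method) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int ox = odim[0], oy = odim[1], oz = odim[2];
  NumericVector out((R_xlen_t)ox * oy * oz);
  for (int k = 0; k < oz; ++k)
    for (int j = 0; j < oy; ++j)
      for (int i = 0; i < ox; ++i) {
        double ux = ((i + 0.5) * out_sp[0]) / in_sp[0] - 0.5;
        double uy = ((j + 0.5) * out_sp[1]) / in_sp[1] - 0.5;
        double uz = ((k + 0.5) * out_sp[2]) / in_sp[2] - 0.5;
        R_xlen_t o = lidx(i, j, k, ox, oy);
        if (method == 1) {
          int ii = (int)std::lround(ux), jj = (int)std::lround(uy), kk = (int)std::lround(uz);
          ii = std::min(std::max(ii, 0), nx - 1);
          jj = std::min(std::max(jj, 0), ny - 1);
          kk = std::min(std::max(kk, 0), nz - 1);
          out[o] = data[lidx(ii, jj, kk, nx, ny)];
        } else {
          int i0 = (int)std::floor(ux), j0 = (int)std::floor(uy), k0 = (int)std::floor(uz);
          double fx = ux - i0, fy = uy - j0, fz = uz - k0;
          double acc = 0.0;
          for (int c = 0; c <= 1; ++c)
            for (int b = 0; b <= 1; ++b)
              for (int a = 0; a <= 1; ++a) {
                int ii = std::min(std::max(i0 + a, 0), nx - 1);
                int jj = std::min(std::max(j0 + b, 0), ny - 1);
                int kk = std::min(std::max(k0 + c, 0), nz - 1);
                double w = (a ? fx : 1 - fx) * (b ? fy : 1 - fy) * (c ? fz : 1 - fz);
                acc += w * data[lidx(ii, jj, kk, nx, ny)];
              }
          out[o] = acc;
        }
      }
  return out;
}

// ---------------------------------------------------------------------------
// Backward warp by a dense displacement field given in voxel units:
// out(x) = in(x + d(x)). method: 0 = trilinear, 1 = nearest neighbour.
// [[Rcpp::export(name = ".cpp_warp")]]
NumericVector cpp_warp(NumericVector data, IntegerVector dim,
                       NumericVector dx, NumericVector dy, NumericVector dz,
                       int method) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out(data.size());
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t v = lidx(i, j, k, nx, ny);
        double ux = i + dx[v], uy = j + dy[v], uz = k + dz[v];
        if (method == 1) {
          int ii = (int)std::lround(ux), jj = (int)std::lround(uy), kk = (int)std::lround(uz);
          ii = std::min(std::max(ii, 0), nx - 1);
          jj = std::min(std::max(jj, 0), ny - 1);
          kk = std::min(std::max(kk, 0), nz - 1);
          out[v] = data[lidx(ii, jj, kk, nx, ny)];
        } else {
          int i0 = (int)std::floor(ux), j0 = (int)std::floor(uy), k0 = (int)std::floor(uz);
          double fx = ux - i0, fy = uy - j0, fz = uz - k0;
          double acc = 0.0;
          for (int c = 0; c <= 1; ++c)
            for (int b = 0; b <= 1; ++b)
              for (int a = 0; a <= 1; ++a) {
                int ii = std::min(std::max(i0 + a, 0), nx - 1);
                int jj = std::min(std::max(j0 + b, 0), ny - 1);
                int kk = std::min(std::max(k0 + c, 0), nz - 1);
                double w = (a ? fx : 1 - fx) * (b ? fy : 1 - fy) * (c ? fz : 1 - fz);
                acc += w * data[lidx(ii, jj, kk, nx, ny)];
              }
          out[v] = acc;
        }
      }
  return out;
}

// ---------------------------------------------------------------------------
// Non-maximum suppression for the 3D Canny detector. The gradient (gx,gy,gz)
// is in mm^-1 units; stepping happens in voxel units, so components are
// divided by the voxel spacing before normalisation. A voxel survives when
// its gradient magnitude is >= the interpolated magnitude one voxel ahead and
// strictly > one voxel behind along the gradient direction.
static double trilin(const NumericVector &d, int nx, int ny, int nz,
                     double ux, double uy, double uz) {
  int i0 = (int)std::floor(ux), j0 = (int)std::floor(uy), k0 = (int)std::floor(uz);
  double fx = ux - i0, fy = uy - j0, fz = uz - k0;
  double acc = 0.0;
  for (int c = 0; c <= 1; ++c)
    for (int b = 0; b <= 1; ++b)
      for (int a = 0; a <= 1; ++a) {
        int ii = std::min(std::max(i0 + a, 0), nx - 1);
        int jj = std::min(std::max(j0 + b, 0), ny - 1);
        int kk = std::min(std::max(k0 + c, 0), nz - 1);
        double w = (a ? fx : 1 - fx) * (b ? fy : 1 - fy) * (c ? fz : 1 - fz);
        acc += w * d[lidx(ii, jj, kk, nx, ny)];
      }
  return acc;
}

// [[Rcpp::export(name = ".cpp_canny_nms")]]
LogicalVector cpp_canny_nms(NumericVector gmag, NumericVector gx, NumericVector gy,
                            NumericVector gz, IntegerVector dim,
                            NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  LogicalVector out(gmag.size(), false);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t v = lidx(i, j, k, nx, ny);
        double m = gmag[v];
        if (m <= 0) continue;
        double vx = gx[v] / spacing[0], vy = gy[v] / spacing[1], vz = gz[v] / spacing[2];
        double nrm = std::sqrt(vx * vx + vy * vy + vz * vz);
        if (nrm <= 0) continue;
        vx /= nrm; vy /= nrm; vz /= nrm;
        double ma = trilin(gmag, nx, ny, nz, i + vx, j + vy, k + vz);
        double mb = trilin(gmag, nx, ny, nz, i - vx, j - vy, k - vz);
        if (m >= ma && m > mb) out[v] = true;
      }
  return out;
}
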