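#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Masked explicit forward-Euler integration of the normalised Fisher-KPP
// equation dc/dt = div(D grad c) + rho c (1 - c) on a regular 3D grid.
// The Laplacian is written in flux form over the 6 voxel faces; a face whose
// neighbour lies outside the brain mask (or the grid) carries zero flux, so
// with rho = 0 the total cell mass is conserved to round-off.
// [[Rcpp::export]]
List fkpp_run_cpp(NumericVector field, LogicalVector brain, IntegerVector dims,
                  NumericVector spacing, double D, double rho, double dt,
                  int nsteps) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> c(field.begin(), field.end());
  std::vector<double> cn(n, 0.0);
  const double wx = D / (spacing[0] * spacing[0]);
  const double wy = D / (spacing[1] * spacing[1]);
  const double wz = D / (spacing[2] * spacing[2]);
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  double clip_total = 0.0;

  for (int s = 0; s < nsteps; ++s) {
    for (int k = 0; k < nz; ++k) {
      for (int j = 0; j < ny; ++j) {
        R_xlen_t base = (R_xlen_t)k * sz + (R_xlen_t)j * sy;
        for (int i = 0; i < nx; ++i) {
          R_xlen_t idx = base + i;
          if (!brain[idx]) { cn[idx] = 0.0; continue; }
          double cc = c[idx];
          double lap = 0.0;
          if (i > 0      && brain[idx - sx]) lap += wx * (c[idx - sx] - cc);
          if (i < nx - 1 && brain[idx + sx]) lap += wx * (c[idx + sx] - cc);
          if (j > 0      && brain[idx - sy]) lap += wy * (c[idx - sy] - cc);
          if (j < ny - 1 && brain[idx + sy]) lap += wy * (c[idx + sy] - cc);
          if (k > 0      && brain[idx - sz]) lap += wz * (c[idx - sz] - cc);
          if (k < nz - 1 && brain[idx + sz]) lap += wz * (c[idx + sz] - cc);
          double v = cc + dt * (lap + rho * cc * (1.0 - cc));
          if (v < 0.0)      { clip_total += -v;      v = 0.0; }
          else if (v > 1.0) { clip_total += v - 1.0; v = 1.0; }
          cn[idx] = v;
        }
      }
    }
    c.swap(cn);
  }

  NumericVector out(n);
  std::copy(c.begin(), c.end(), out.begin());
  out.attr("dim") = dims;
  return List::create(_["field"] = out, _["clip_total"] = clip_total);
}

// 1D squared-distance transform (lower envelope of parabolas,
// Felzenszwalb & Huttenlocher) sampled at grid step w.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z, int n, double w) {
  const double INF = std::numeric_limits<double>::infinity();
  int k = -1;
  for (int q = 0; q < n; ++q) {
    if (f[q] == INF) continue; // infinite parabolas never form the envelope
    double qq = q * w;
    if (k < 0) {
      k = 0; v[0] = q; z[0] = -INF; z[1] = INF;
      continue;
    }
    double s;
    while (true) {
      double vv = v[k] * w;
      s = ((f[q] + qq * qq) - (f[v[k]] + vv * vv)) / (2.0 * qq - 2.0 * vv);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  if (k < 0) { // no finite sample along this line
    for (int q = 0; q < n; ++q) d[q] = INF;
    return;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double qq = q * w;
    while (z[k + 1] < qq) ++k;
    double vv = v[k] * w;
    d[q] = (qq - vv) * (qq - vv) + f[v[k]];
  }
}

// Exact Euclidean distance transform (mm) on an anisotropic voxel grid:
// distance from every voxel centre to the nearest TRUE voxel centre.
// Voxels where mask is TRUE get 0; if the mask is empty the result is Inf.
// [[Rcpp::export]]
NumericVector edt_mm_cpp(LogicalVector mask, IntegerVector dims,
                         NumericVector spacing) {
  const double INF = std::numeric_limits<double>::infinity();
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> g(n);
  for (R_xlen_t i = 0; i < n; ++i) g[i] = mask[i] ? 0.0 : INF;

  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = k * sz + (R_xlen_t)j * sy;
      for (int i = 0; i < nx; ++i) f[i] = g[base + i * sx];
      dt1d(f, d, v, z, nx, spacing[0]);
      for (int i = 0; i < nx; ++i) g[base + i * sx] = d[i];
    }
  // pass along y
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = k * sz + (R_xlen_t)i * sx;
      for (int j = 0; j < ny; ++j) f[j] = g[base + j * sy];
      dt1d(f, d, v, z, ny, spacing[1]);
      for (int j = 0; j < ny; ++j) g[base + j * sy] = d[j];
    }
  // pass along z
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = (R_xlen_t)j * sy + (R_xlen_t)i * sx;
      for (int k = 0; k < nz; ++k) f[k] = g[base + k * sz];
      dt1d(f, d, v, z, nz, spacing[2]);
      for (int k = 0; k < nz; ++k) g[base + k * sz] = d[k];
    }

  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = std::isinf(g[i]) ? R_PosInf : std::sqrt(g[i]);
  out.attr("dim") = dims;
  return out;
}

// One 6-connected (face-adjacent) binary erosion: a voxel survives iff it and
// all six face neighbours are foreground; outside the grid counts as
// background.
// [[Rcpp::export]]
LogicalVector erode6_cpp(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  LogicalVector out((R_xlen_t)nx * ny * nz);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = (R_xlen_t)k * sz + (R_xlen_t)j * sy;
      for (int i = 0; i < nx; ++i) {
        R_xlen_t idx = base + i;
        bool keep = mask[idx] &&
          i > 0 && mask[idx - sx] && i < nx - 1 && mask[idx + sx] &&
          j > 0 && mask[idx - sy] && j < ny - 1 && mask[idx + sy] &&
          k > 0 && mask[idx - sz] && k < nz - 1 && mask[idx + sz];
        out[idx] = keep;
      }
    }
  out.attr("dim") = dims;
  return out;
}
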