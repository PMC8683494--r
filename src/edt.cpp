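#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Felzenszwalb & Huttenlocher lower-envelope distance transform along one
// axis; `w` is the physical sample spacing so anisotropic voxels are exact.
static void dt1d(std::vector<double> &f, int n, double w) {
  if (n == 1) return;
  std::vector<int> v(n);
  std::vector<double> z(n + 1), d(n);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double xq = q * w;
    double s;
    while (true) {
      double xv = v[k] * w;
      s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2.0 * (xq - xv));
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * w;
    while (z[k + 1] < xq) ++k;
    double dx = xq - v[k] * w;
    d[q] = dx * dx + f[v[k]];
  }
  for (int q = 0; q < n; ++q) f[q] = d[q];
}

// Squared Euclidean distance (mm^2) from every voxel center to the nearest
// voxel center where mask is TRUE. Voxels where mask is TRUE get 0.
// [[Rcpp::export(name = ".edt_squared_cpp")]]
NumericVector edt_squared_cpp(LogicalVector mask, IntegerVector dim,
                              NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  // large finite sentinel: keeps the lower-envelope recursion well defined
  // (infinities make the parabola intersections NaN); mapped back to Inf
  // on output
  const double BIG = 1e20;
  NumericVector out(mask.size());
  for (R_xlen_t i = 0; i < mask.size(); ++i)
    out[i] = mask[i] ? 0.0 : BIG;

  std::vector<double> line;
  // x pass
  line.resize(nx);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx;
      for (int i = 0; i < nx; ++i) line[i] = out[base + i];
      dt1d(line, nx, spacing[0]);
      for (int i = 0; i < nx; ++i) out[base + i] = line[i];
    }
  // y pass
  line.resize(ny);
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = (R_xlen_t)k * nx * ny + i;
      for (int j = 0; j < ny; ++j) line[j] = out[base + (R_xlen_t)j * nx];
      dt1d(line, ny, spacing[1]);
      for (int j = 0; j < ny; ++j) out[base + (R_xlen_t)j * nx] = line[j];
    }
  // z pass
  line.resize(nz);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = (R_xlen_t)j * nx + i;
      for (int k = 0; k < nz; ++k) line[k] = out[base + (R_xlen_t)k * nx * ny];
      dt1d(line, nz, spacing[2]);
      for (int k = 0; k < nz; ++k) out[base + (R_xlen_t)k * nx * ny] = line[k];
    }
  for (R_xlen_t i = 0; i < out.size(); ++i)
    if (out[i] >= 1e19) out[i] = R_PosInf;
  out.attr("dim") = dim;
  return out;
}

// Fill interior holes of a binary volume: background voxels not reachable
// from the array border by 6-connected steps become foreground.
// [[Rcpp::export(name = ".fill_holes_cpp")]]
LogicalVector fill_holes_cpp(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<char> outside(n, 0);
  std::queue<R_xlen_t> q;
  auto idx = [&](int i, int j, int k) {
    return (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx + i;
  };
  auto push = [&](int i, int j, int k) {
    R_xlen_t id = idx(i, j, k);
    if (!outside[id] && !mask[id]) { outside[id] = 1; q.push(id); }
  };
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) { push(i, j, 0); push(i, j, nz - 1); }
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) { push(i, 0, k); push(i, ny - 1, k); }
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) { push(0, j, k); push(nx - 1, j, k); }
  while (!q.empty()) {
    R_xlen_t id = q.front(); q.pop();
    int i = (int)(id % nx);
    int j = (int)((id / nx) % ny);
    int k = (int)(id / ((R_xlen_t)nx * ny));
    if (i > 0) push(i - 1, j, k);
    if (i < nx - 1) push(i + 1, j, k);
    if (j > 0) push(i, j - 1, k);
    if (j < ny - 1) push(i, j + 1, k);
    if (k > 0) push(i, j, k - 1);
    if (k < nz - 1) push(i, j, k + 1);
  }
  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] || !outside[i];
  out.attr("dim") = dim;
  return out;
}

// Minimum Euclidean distance (mm) from every voxel center to a set of
// contact centers, clamped to +Inf beyond rmax. One pass over each
// contact's bounding box, so the full radius sweep needs a single field.
// [[Rcpp::export(name = ".contact_distance_field_cpp")]]
NumericVector contact_distance_field_cpp(IntegerVector dim,
                                         NumericVector spacing,
                                         NumericVector origin,
                                         NumericMatrix centers,
                                         double rmax) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n, R_PosInf);
  const double r2max = rmax * rmax;
  for (int c = 0; c < centers.nrow(); ++c) {
    const double cx = centers(c, 0), cy = centers(c, 1), cz = centers(c, 2);
    int i0 = (int)std::ceil((cx - rmax - origin[0]) / spacing[0]);
    int i1 = (int)std::floor((cx + rmax - origin[0]) / spacing[0]);
    int j0 = (int)std::ceil((cy - rmax - origin[1]) / spacing[1]);
    int j1 = (int)std::floor((cy + rmax - origin[1]) / spacing[1]);
    int k0 = (int)std::ceil((cz - rmax - origin[2]) / spacing[2]);
    int k1 = (int)std::floor((cz + rmax - origin[2]) / spacing[2]);
    i0 = std::max(i0, 0); i1 = std::min(i1, nx - 1);
    j0 = std::max(j0, 0); j1 = std::min(j1, ny - 1);
    k0 = std::max(k0, 0); k1 = std::min(k1, nz - 1);
    for (int k = k0; k <= k1; ++k) {
      double dz = origin[2] + k * spacing[2] - cz;
      for (int j = j0; j <= j1; ++j) {
        double dy = origin[1] + j * spacing[1] - cy;
        double dyz2 = dy * dy + dz * dz;
        if (dyz2 > r2max) continue;
        R_xlen_t base = (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx;
        for (int i = i0; i <= i1; ++i) {
          double dx = origin[0] + i * spacing[0] - cx;
          double d2 = dx * dx + dyz2;
          if (d2 > r2max) continue;
          double d = std::sqrt(d2);
          if (d < out[base + i]) out[base + i] = d;
        }
      }
    }
  }
  out.attr("dim") = dim;
  return out;
}
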