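// Exact 3D Euclidean distance transform on an anisotropic voxel grid.
// Lower-envelope-of-parabolas algorithm applied separably per axis, with
// sample positions at physical voxel-center coordinates (index * spacing),
// so the result is exact in millimetres for any spacing triple.
#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// 1D squared-distance transform: d[i] = min_j f[j] + (s*(i-j))^2
static void dt1d(const std::vector<double>& f, double s,
                 std::vector<double>& d, std::vector<int>& v,
                 std::vector<double>& z) {
  int n = (int)f.size();
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    if (f[q] == INF) continue;
    double xq = q * s;
    while (true) {
      if (f[v[k]] == INF) { // first finite parabola
        k--;
        if (k < 0) { k = 0; v[0] = q; z[0] = -INF; z[1] = INF; goto placed; }
        continue;
      }
      double xv = v[k] * s;
      double inter = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) /
                     (2.0 * (xq - xv));
      if (inter <= z[k]) {
        k--;
        if (k < 0) { k = 0; v[0] = q; z[0] = -INF; z[1] = INF; goto placed; }
      } else {
        k++;
        v[k] = q;
        z[k] = inter;
        z[k + 1] = INF;
        goto placed;
      }
    }
    placed:;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * s;
    while (z[k + 1] < xq) k++;
    double xv = v[k] * s;
    d[q] = (f[v[k]] == INF) ? INF : f[v[k]] + (xq - xv) * (xq - xv);
  }
}

// [[Rcpp::export(name = ".cpp_edt3d")]]
NumericVector cpp_edt3d(LogicalVector mask, NumericVector spacing) {
  IntegerVector dm = mask.attr("dim");
  if (dm.size() != 3) stop("mask must be a 3-d array");
  int nx = dm[0], ny = dm[1], nz = dm[2];
  if (spacing.size() != 3) stop("spacing must have length 3");
  NumericVector out(Dimension(nx, ny, nz));
  // init: 0 on feature voxels, INF elsewhere
  for (R_xlen_t i = 0; i < mask.size(); ++i)
    out[i] = (mask[i] == TRUE) ? 0.0 : INF;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x (fastest index)
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      double* line = out.begin() + (size_t)k * nx * ny + (size_t)j * nx;
      bool any = false;
      for (int i = 0; i < nx; ++i) { f[i] = line[i]; if (f[i] < INF) any = true; }
      if (!any) continue;
      f.resize(nx); d.resize(nx);
      dt1d(f, spacing[0], d, v, z);
      for (int i = 0; i < nx; ++i) line[i] = d[i];
      f.resize(nmax); d.resize(nmax);
    }
  // pass along y
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      double* base = out.begin() + (size_t)k * nx * ny + i;
      bool any = false;
      for (int j = 0; j < ny; ++j) { f[j] = base[(size_t)j * nx]; if (f[j] < INF) any = true; }
      if (!any) continue;
      f.resize(ny); d.resize(ny);
      dt1d(f, spacing[1], d, v, z);
      for (int j = 0; j < ny; ++j) base[(size_t)j * nx] = d[j];
      f.resize(nmax); d.resize(nmax);
    }
  // pass along z
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      double* base = out.begin() + (size_t)j * nx + i;
      bool any = false;
      for (int k = 0; k < nz; ++k) { f[k] = base[(size_t)k * nx * ny]; if (f[k] < INF) any = true; }
      if (!any) continue;
      f.resize(nz); d.resize(nz);
      dt1d(f, spacing[2], d, v, z);
      for (int k = 0; k < nz; ++k) base[(size_t)k * nx * ny] = d[k];
      f.resize(nmax); d.resize(nmax);
    }

  for (R_xlen_t i = 0; i < out.size(); ++i)
    out[i] = (out[i] == INF) ? INF : std::sqrt(out[i]);
  return out;
}
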