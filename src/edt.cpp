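#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Exact Euclidean distance transform with anisotropic voxel spacing,
// lower-envelope (parabola) algorithm applied separably per axis on squared
// distances. Alongside the distance, the identity of the nearest seed voxel
// is propagated so contacts can later be assigned to a labelled source.

static const double INF = std::numeric_limits<double>::infinity();

// One 1-D pass. f: squared distances at positions i*step; src: index of the
// originating seed (carried payload). Writes results into d / dsrc.
static void dt1d(const std::vector<double> &f, const std::vector<int> &src,
                 double step, int n,
                 std::vector<double> &d, std::vector<int> &dsrc) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  // find first finite parabola
  int q0 = 0;
  while (q0 < n && f[q0] == INF) ++q0;
  if (q0 == n) { // nothing reachable on this scan line
    for (int q = 0; q < n; ++q) { d[q] = INF; dsrc[q] = NA_INTEGER; }
    return;
  }
  v[0] = q0; z[0] = -INF; z[1] = INF;
  for (int q = q0 + 1; q < n; ++q) {
    if (f[q] == INF) continue;
    double xq = q * step;
    double s;
    while (true) {
      double xv = v[k] * step;
      s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2.0 * (xq - xv));
      if (s <= z[k]) { --k; } else break;
    }
    ++k; v[k] = q; z[k] = s; z[k + 1] = INF;
  }
  int kk = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * step;
    while (z[kk + 1] < xq) ++kk;
    double dx = xq - v[kk] * step;
    d[q] = dx * dx + f[v[kk]];
    dsrc[q] = src[v[kk]];
  }
}

// seeds: integer array (0 = background) of dim (ny, nx, nz); spacing c(sy, sx, sz).
// Returns squared distances (same dim) and the label of the nearest seed voxel.
// [[Rcpp::export]]
List cpp_edt(IntegerVector seeds, IntegerVector dim, NumericVector spacing) {
  int ny = dim[0], nx = dim[1], nz = dim[2];
  R_xlen_t nn = (R_xlen_t)ny * nx * nz;
  NumericVector d2(nn);
  IntegerVector near(nn);
  // voxel -> its own linear index if seed, else INF
  for (R_xlen_t i = 0; i < nn; ++i) {
    if (seeds[i] > 0) { d2[i] = 0.0; near[i] = (int)i; }
    else { d2[i] = INF; near[i] = NA_INTEGER; }
  }
  int nmax = std::max(ny, std::max(nx, nz));
  std::vector<double> f(nmax), dcol(nmax);
  std::vector<int> s(nmax), scol(nmax);

  // pass along y (fastest index), step spacing[0]
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < nx; ++j) {
      R_xlen_t base = (R_xlen_t)k * nx * ny + (R_xlen_t)j * ny;
      for (int i = 0; i < ny; ++i) { f[i] = d2[base + i]; s[i] = near[base + i]; }
      dt1d(f, s, spacing[0], ny, dcol, scol);
      for (int i = 0; i < ny; ++i) { d2[base + i] = dcol[i]; near[base + i] = scol[i]; }
    }
  // pass along x, step spacing[1]
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < ny; ++i) {
      R_xlen_t base = (R_xlen_t)k * nx * ny + i;
      for (int j = 0; j < nx; ++j) { f[j] = d2[base + (R_xlen_t)j * ny]; s[j] = near[base + (R_xlen_t)j * ny]; }
      dt1d(f, s, spacing[1], nx, dcol, scol);
      for (int j = 0; j < nx; ++j) { d2[base + (R_xlen_t)j * ny] = dcol[j]; near[base + (R_xlen_t)j * ny] = scol[j]; }
    }
  // pass along z, step spacing[2]
  R_xlen_t stride = (R_xlen_t)nx * ny;
  for (int j = 0; j < nx; ++j)
    for (int i = 0; i < ny; ++i) {
      R_xlen_t base = (R_xlen_t)j * ny + i;
      for (int k = 0; k < nz; ++k) { f[k] = d2[base + k * stride]; s[k] = near[base + k * stride]; }
      dt1d(f, s, spacing[2], nz, dcol, scol);
      for (int k = 0; k < nz; ++k) { d2[base + k * stride] = dcol[k]; near[base + k * stride] = scol[k]; }
    }

  // map nearest seed voxel index -> its label
  IntegerVector nlab(nn);
  for (R_xlen_t i = 0; i < nn; ++i)
    nlab[i] = (near[i] == NA_INTEGER) ? NA_INTEGER : seeds[near[i]];
  return List::create(_["dist2"] = d2, _["nearest_label"] = nlab);
}
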