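#include <Rcpp.h>
#include <vector>
#include <limits>

using namespace Rcpp;

// 1D squared distance transform, Felzenszwalb & Huttenlocher lower envelope.
static void dt1d(const double* f, double* d, int n,
                 std::vector<int>& v, std::vector<double>& z) {
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; q++) {
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      k--;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    double dq = q - v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Squared Euclidean distance (in voxel units) from every foreground voxel to
// the nearest background voxel. mask: logical array, dims nx,ny,nz (column
// major). Background voxels get 0. The array border is NOT implicitly
// background; pad in the caller if that is wanted.
// [[Rcpp::export(name = ".edt3d_sq")]]
NumericVector edt3d_sq(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  // large finite sentinel: infinity would give NaN in the envelope
  // intersection formula on all-foreground scan lines
  const double BIG = 1e20;
  R_xlen_t ntot = (R_xlen_t)nx * ny * nz;
  NumericVector out(ntot);
  for (R_xlen_t i = 0; i < ntot; i++) out[i] = mask[i] ? BIG : 0.0;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax);
  std::vector<int> v(nmax);
  std::vector<double> z(nmax + 1);

  // pass along x
  for (int kz = 0; kz < nz; kz++)
    for (int ky = 0; ky < ny; ky++) {
      R_xlen_t base = (R_xlen_t)kz * nx * ny + (R_xlen_t)ky * nx;
      for (int i = 0; i < nx; i++) f[i] = out[base + i];
      dt1d(f.data(), d.data(), nx, v, z);
      for (int i = 0; i < nx; i++) out[base + i] = d[i];
    }
  // pass along y
  for (int kz = 0; kz < nz; kz++)
    for (int kx = 0; kx < nx; kx++) {
      R_xlen_t base = (R_xlen_t)kz * nx * ny + kx;
      for (int i = 0; i < ny; i++) f[i] = out[base + (R_xlen_t)i * nx];
      dt1d(f.data(), d.data(), ny, v, z);
      for (int i = 0; i < ny; i++) out[base + (R_xlen_t)i * nx] = d[i];
    }
  // pass along z
  R_xlen_t sz = (R_xlen_t)nx * ny;
  for (int ky = 0; ky < ny; ky++)
    for (int kx = 0; kx < nx; kx++) {
      R_xlen_t base = (R_xlen_t)ky * nx + kx;
      for (int i = 0; i < nz; i++) f[i] = out[base + (R_xlen_t)i * sz];
      dt1d(f.data(), d.data(), nz, v, z);
      for (int i = 0; i < nz; i++) out[base + (R_xlen_t)i * sz] = d[i];
    }
  out.attr("dim") = dims;
  return out;
}
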