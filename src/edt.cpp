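#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Felzenszwalb & Huttenlocher lower-envelope 1D squared distance transform.
// f: sampled squared distances; d: output; v, z: work arrays (size n, n+1).
static void dt1d(const double *f, double *d, int *v, double *z, int n) {
  const double INF = 1e30;
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
    while (z[k + 1] < (double)q) k++;
    double dq = (double)q - v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Exact squared Euclidean distance (in voxel units) from every voxel to the
// nearest TRUE voxel of `mask`. Column-major 3D layout, dims = (n1, n2, n3).
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector mask, IntegerVector dims) {
  const double INF = 1e30;
  int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; i++) out[i] = mask[i] ? 0.0 : INF;

  int nmax = std::max(n1, std::max(n2, n3));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // axis 1 (fastest-varying)
  for (int k = 0; k < n3; k++)
    for (int j = 0; j < n2; j++) {
      R_xlen_t base = (R_xlen_t)n1 * (j + (R_xlen_t)n2 * k);
      for (int i = 0; i < n1; i++) f[i] = out[base + i];
      dt1d(f.data(), d.data(), v.data(), z.data(), n1);
      for (int i = 0; i < n1; i++) out[base + i] = d[i];
    }
  // axis 2
  for (int k = 0; k < n3; k++)
    for (int i = 0; i < n1; i++) {
      R_xlen_t base = i + (R_xlen_t)n1 * n2 * k;
      for (int j = 0; j < n2; j++) f[j] = out[base + (R_xlen_t)n1 * j];
      dt1d(f.data(), d.data(), v.data(), z.data(), n2);
      for (int j = 0; j < n2; j++) out[base + (R_xlen_t)n1 * j] = d[j];
    }
  // axis 3
  R_xlen_t stride3 = (R_xlen_t)n1 * n2;
  for (int j = 0; j < n2; j++)
    for (int i = 0; i < n1; i++) {
      R_xlen_t base = i + (R_xlen_t)n1 * j;
      for (int k = 0; k < n3; k++) f[k] = out[base + stride3 * k];
      dt1d(f.data(), d.data(), v.data(), z.data(), n3);
      for (int k = 0; k < n3; k++) out[base + stride3 * k] = d[k];
    }
  return out;
}

// Local thickness (Hildebrand-Ruegsegger): per foreground voxel, the diameter
// of the largest inscribed sphere containing it. `radius` is the EDT of the
// foreground (voxel units, distance to nearest background voxel). Spheres are
// painted in decreasing radius order; the first writer at a voxel is maximal.
// [[Rcpp::export]]
NumericVector cpp_local_thickness(NumericVector radius, LogicalVector mask,
                                  IntegerVector dims) {
  int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  NumericVector th(n);

  std::vector<R_xlen_t> fg;
  fg.reserve(n / 4);
  for (R_xlen_t i = 0; i < n; i++)
    if (mask[i]) fg.push_back(i);
  std::sort(fg.begin(), fg.end(), [&](R_xlen_t a, R_xlen_t b) {
    return radius[a] > radius[b];
  });

  R_xlen_t s12 = (R_xlen_t)n1 * n2;
  for (R_xlen_t idx : fg) {
    double r = radius[idx];
    if (r <= 0) continue;
    int i0 = (int)(idx % n1);
    int j0 = (int)((idx / n1) % n2);
    int k0 = (int)(idx / s12);
    int ri = (int)std::floor(r);
    double r2 = r * r;
    int klo = std::max(0, k0 - ri), khi = std::min(n3 - 1, k0 + ri);
    int jlo = std::max(0, j0 - ri), jhi = std::min(n2 - 1, j0 + ri);
    int ilo = std::max(0, i0 - ri), ihi = std::min(n1 - 1, i0 + ri);
    for (int k = klo; k <= khi; k++) {
      double dk = (double)(k - k0) * (k - k0);
      for (int j = jlo; j <= jhi; j++) {
        double dj = (double)(j - j0) * (j - j0);
        if (dk + dj > r2) continue;
        R_xlen_t base = (R_xlen_t)n1 * j + s12 * k;
        for (int i = ilo; i <= ihi; i++) {
          double di = (double)(i - i0) * (i - i0);
          if (dk + dj + di <= r2) {
            R_xlen_t u = base + i;
            if (th[u] == 0.0) th[u] = 2.0 * r;
          }
        }
      }
    }
  }
  return th;
}
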