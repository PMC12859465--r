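#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>

using namespace Rcpp;

// Separable squared Euclidean distance transform (Felzenszwalb & Huttenlocher,
// Theory of Computing 2012). Distances are in voxel units; the grid is assumed
// isotropic. Input layout is R column-major with dims (n1, n2, n3); a 2D image
// is passed with n3 = 1.

static const double INF = std::numeric_limits<double>::infinity();

// 1D squared distance transform of sampled function f (lower envelope of
// parabolas). n values, result written back into f via buffers.
static void dt1d(std::vector<double> &f, std::vector<double> &d,
                 std::vector<int> &v, std::vector<double> &z, int n) {
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; q++) {
    if (f[q] == INF) continue;
    if (k == 0 && f[v[0]] == INF) { v[0] = q; continue; }
    double s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (k > 0 && s <= z[k]) {
      k--;
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  if (f[v[0]] == INF) {  // no finite sample on this line
    for (int q = 0; q < n; q++) d[q] = INF;
  } else {
    int j = 0;
    for (int q = 0; q < n; q++) {
      while (z[j + 1] < q) j++;
      double dq = q - (double)v[j];
      d[q] = dq * dq + f[v[j]];
    }
  }
  for (int q = 0; q < n; q++) f[q] = d[q];
}

// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector mask, IntegerVector dims) {
  int n1 = dims[0], n2 = dims[1], n3 = dims.size() > 2 ? dims[2] : 1;
  R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; i++) out[i] = mask[i] ? 0.0 : INF;

  int nmax = std::max(n1, std::max(n2, n3));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // axis 1 (fastest varying)
  if (n1 > 1) {
    for (int k = 0; k < n3; k++)
      for (int j = 0; j < n2; j++) {
        R_xlen_t base = (R_xlen_t)k * n1 * n2 + (R_xlen_t)j * n1;
        for (int i = 0; i < n1; i++) f[i] = out[base + i];
        dt1d(f, d, v, z, n1);
        for (int i = 0; i < n1; i++) out[base + i] = f[i];
      }
  }
  // axis 2
  if (n2 > 1) {
    for (int k = 0; k < n3; k++)
      for (int i = 0; i < n1; i++) {
        R_xlen_t base = (R_xlen_t)k * n1 * n2 + i;
        for (int j = 0; j < n2; j++) f[j] = out[base + (R_xlen_t)j * n1];
        dt1d(f, d, v, z, n2);
        for (int j = 0; j < n2; j++) out[base + (R_xlen_t)j * n1] = f[j];
      }
  }
  // axis 3
  if (n3 > 1) {
    R_xlen_t plane = (R_xlen_t)n1 * n2;
    for (int j = 0; j < n2; j++)
      for (int i = 0; i < n1; i++) {
        R_xlen_t base = (R_xlen_t)j * n1 + i;
        for (int k = 0; k < n3; k++) f[k] = out[base + (R_xlen_t)k * plane];
        dt1d(f, d, v, z, n3);
        for (int k = 0; k < n3; k++) out[base + (R_xlen_t)k * plane] = f[k];
      }
  }
  return out;
}

// Connected component labeling on a binary grid, 26- or 6-connectivity in 3D
// (degenerates to 8-/4-connectivity when n3 == 1). Iterative flood fill.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  int n1 = dims[0], n2 = dims[1], n3 = dims.size() > 2 ? dims[2] : 1;
  R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  IntegerVector lab(n, 0);

  std::vector<std::array<int, 3> > offs;
  for (int dk = -1; dk <= 1; dk++)
    for (int dj = -1; dj <= 1; dj++)
      for (int di = -1; di <= 1; di++) {
        if (di == 0 && dj == 0 && dk == 0) continue;
        int manh = std::abs(di) + std::abs(dj) + std::abs(dk);
        if (connectivity == 6 && manh != 1) continue;
        offs.push_back({{di, dj, dk}});
      }

  std::vector<R_xlen_t> stack;
  int next = 0;
  R_xlen_t plane = (R_xlen_t)n1 * n2;
  for (R_xlen_t s = 0; s < n; s++) {
    if (!mask[s] || lab[s] != 0) continue;
    next++;
    lab[s] = next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t p = stack.back();
      stack.pop_back();
      int k = (int)(p / plane);
      int rem = (int)(p % plane);
      int j = rem / n1;
      int i = rem % n1;
      for (size_t o = 0; o < offs.size(); o++) {
        int ii = i + offs[o][0], jj = j + offs[o][1], kk = k + offs[o][2];
        if (ii < 0 || ii >= n1 || jj < 0 || jj >= n2 || kk < 0 || kk >= n3)
          continue;
        R_xlen_t q = (R_xlen_t)kk * plane + (R_xlen_t)jj * n1 + ii;
        if (mask[q] && lab[q] == 0) {
          lab[q] = next;
          stack.push_back(q);
        }
      }
    }
  }
  return lab;
}
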