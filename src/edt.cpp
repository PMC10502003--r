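#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>

using namespace Rcpp;

// Separable exact squared Euclidean distance transform
// (Felzenszwalb & Huttenlocher lower-envelope-of-parabolas algorithm),
// generalised to anisotropic sample spacing: each axis pass uses the
// physical spacing of that axis, so the result is exact in mm.

static const double INF = std::numeric_limits<double>::infinity();

// one 1-D pass: f = input squared distances, d = output, n = length,
// w = sample spacing along this axis.  Entries with f == +inf carry no
// parabola; only finite entries enter the lower envelope.
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n,
                 double w, std::vector<int>& v, std::vector<double>& z) {
  const double w2 = w * w;
  int k = -1;
  for (int q = 0; q < n; ++q) {
    if (f[q] == INF) continue;
    if (k < 0) {
      k = 0;
      v[0] = q;
      z[0] = -INF;
      z[1] = INF;
      continue;
    }
    int p = v[k];
    double s = ((f[q] + w2 * q * q) - (f[p] + w2 * p * p)) / (2.0 * w2 * (q - p));
    while (k > 0 && s <= z[k]) {
      --k;
      p = v[k];
      s = ((f[q] + w2 * q * q) - (f[p] + w2 * p * p)) / (2.0 * w2 * (q - p));
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  if (k < 0) {  // no finite parabola in this line
    for (int q = 0; q < n; ++q) d[q] = INF;
    return;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    int p = v[k];
    double dq = w * (q - p);
    d[q] = dq * dq + f[p];
  }
}

// [[Rcpp::export(name = ".edt3d_cpp")]]
NumericVector edt3d_cpp(LogicalVector sites, IntegerVector dims,
                        NumericVector spacing) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t N = (R_xlen_t)n1 * n2 * n3;
  NumericVector out(N);
  // init: 0 at sites, +inf elsewhere
  for (R_xlen_t i = 0; i < N; ++i) out[i] = sites[i] ? 0.0 : INF;

  int nmax = std::max(n1, std::max(n2, n3));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along axis 1 (stride 1)
  for (int k = 0; k < n3; ++k) {
    for (int j = 0; j < n2; ++j) {
      R_xlen_t base = (R_xlen_t)k * n1 * n2 + (R_xlen_t)j * n1;
      bool any = false;
      for (int i = 0; i < n1; ++i) { f[i] = out[base + i]; if (f[i] < INF) any = true; }
      if (!any) continue;
      dt1d(f, d, n1, spacing[0], v, z);
      for (int i = 0; i < n1; ++i) out[base + i] = d[i];
    }
  }
  // pass along axis 2 (stride n1)
  for (int k = 0; k < n3; ++k) {
    for (int i = 0; i < n1; ++i) {
      R_xlen_t base = (R_xlen_t)k * n1 * n2 + i;
      bool any = false;
      for (int j = 0; j < n2; ++j) { f[j] = out[base + (R_xlen_t)j * n1]; if (f[j] < INF) any = true; }
      if (!any) continue;
      dt1d(f, d, n2, spacing[1], v, z);
      for (int j = 0; j < n2; ++j) out[base + (R_xlen_t)j * n1] = d[j];
    }
  }
  // pass along axis 3 (stride n1*n2)
  const R_xlen_t s3 = (R_xlen_t)n1 * n2;
  for (int j = 0; j < n2; ++j) {
    for (int i = 0; i < n1; ++i) {
      R_xlen_t base = (R_xlen_t)j * n1 + i;
      bool any = false;
      for (int k = 0; k < n3; ++k) { f[k] = out[base + (R_xlen_t)k * s3]; if (f[k] < INF) any = true; }
      if (!any) continue;
      dt1d(f, d, n3, spacing[2], v, z);
      for (int k = 0; k < n3; ++k) out[base + (R_xlen_t)k * s3] = d[k];
    }
  }
  // squared -> euclidean
  for (R_xlen_t i = 0; i < N; ++i) out[i] = std::sqrt(out[i]);
  return out;
}

// 6-connectivity component labelling of a 3-D logical grid.
// Labels are 1..K in order of first (column-major) encounter; background 0.

// [[Rcpp::export(name = ".label6_cpp")]]
IntegerVector label6_cpp(LogicalVector mask, IntegerVector dims) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t N = (R_xlen_t)n1 * n2 * n3;
  IntegerVector lab(N, 0);
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t s = 0; s < N; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      int i = (int)(cur % n1);
      int j = (int)((cur / n1) % n2);
      int k = (int)(cur / ((R_xlen_t)n1 * n2));
      const int di[6] = {-1, 1, 0, 0, 0, 0};
      const int dj[6] = {0, 0, -1, 1, 0, 0};
      const int dk[6] = {0, 0, 0, 0, -1, 1};
      for (int t = 0; t < 6; ++t) {
        int ii = i + di[t], jj = j + dj[t], kk = k + dk[t];
        if (ii < 0 || ii >= n1 || jj < 0 || jj >= n2 || kk < 0 || kk >= n3) continue;
        R_xlen_t nb = (R_xlen_t)kk * n1 * n2 + (R_xlen_t)jj * n1 + ii;
        if (mask[nb] && lab[nb] == 0) {
          lab[nb] = next;
          stack.push_back(nb);
        }
      }
    }
  }
  return lab;
}
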