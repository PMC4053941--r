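#include <Rcpp.h>
#include <vector>

// Exact squared Euclidean distance transform by separable 1D lower-envelope
// passes (Felzenszwalb & Huttenlocher), with per-axis sample spacing so
// anisotropic voxels are handled in physical units. Background voxels are
// seeds (distance 0); the caller pads the array with a background border,
// which bounds every true distance by the padded diagonal and lets a large
// finite sentinel stand in for +Inf.

static void dt1d(const double *f, double *d, int n, double step,
                 std::vector<int> &v, std::vector<double> &z,
                 double inf) {
  int k = 0;
  v[0] = 0;
  z[0] = -inf;
  z[1] = inf;
  for (int q = 1; q < n; q++) {
    double xq = q * step;
    double s;
    while (true) {
      double xv = v[k] * step;
      s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2.0 * (xq - xv));
      if (k > 0 && s <= z[k]) k--; else break;
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = inf;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    double xq = q * step;
    while (z[k + 1] < xq) k++;
    double xv = v[k] * step;
    d[q] = (xq - xv) * (xq - xv) + f[v[k]];
  }
}

// [[Rcpp::export(name = ".edt_sq_cpp")]]
Rcpp::NumericVector edt_sq_cpp(Rcpp::LogicalVector mask,
                               Rcpp::IntegerVector dims,
                               Rcpp::NumericVector spacing) {
  int nd = dims.size();
  if (nd != spacing.size()) Rcpp::stop("dims/spacing length mismatch");
  R_xlen_t n = 1;
  double diag = 0.0;
  for (int i = 0; i < nd; i++) {
    n *= dims[i];
    diag += dims[i] * spacing[i];
  }
  if (n != mask.size()) Rcpp::stop("mask length does not match dims");
  const double SENTINEL = 16.0 * diag * diag + 1.0; // > any true sq. distance

  std::vector<double> d(n);
  for (R_xlen_t i = 0; i < n; i++) d[i] = mask[i] ? SENTINEL : 0.0;

  R_xlen_t stride = 1;
  for (int dim = 0; dim < nd; dim++) {
    int len = dims[dim];
    if (len > 1) {
      R_xlen_t nlines = n / len;
      std::vector<double> f(len), out(len);
      std::vector<int> v(len);
      std::vector<double> z(len + 1);
      for (R_xlen_t line = 0; line < nlines; line++) {
        R_xlen_t inner = line % stride;
        R_xlen_t outer = line / stride;
        R_xlen_t base = inner + outer * stride * len;
        for (int j = 0; j < len; j++) f[j] = d[base + (R_xlen_t)j * stride];
        dt1d(f.data(), out.data(), len, spacing[dim], v, z, 1e300);
        for (int j = 0; j < len; j++) d[base + (R_xlen_t)j * stride] = out[j];
      }
    }
    stride *= len;
  }

  Rcpp::NumericVector res(n);
  for (R_xlen_t i = 0; i < n; i++) res[i] = d[i];
  res.attr("dim") = dims;
  return res;
}
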