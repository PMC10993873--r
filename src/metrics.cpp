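#include <Rcpp.h>
using namespace Rcpp;

// Per-column selection metrics of candidate residue reconstructions:
// oscillation-index numerator sum |r(k) - 2 r(k+1) + r(k+2)| and maximum
// over the first L samples, and the minimum over all rows. One pass per
// column; called once per truncation candidate, so this is the inner loop
// of the deconvolution.
// [[Rcpp::export(name = ".residue_metrics")]]
List residue_metrics(const NumericMatrix& R, const int L) {
  const int n = R.nrow(), p = R.ncol();
  if (L < 3 || L > n) stop("invalid L");
  NumericVector d2sum(p), maxL(p), minAll(p);
  for (int j = 0; j < p; ++j) {
    const double* col = &R(0, j);
    double mx = col[0], mn = col[0], acc = 0.0;
    for (int i = 0; i + 2 < L; ++i) {
      double d = col[i] - 2.0 * col[i + 1] + col[i + 2];
      acc += d < 0 ? -d : d;
    }
    for (int i = 1; i < L; ++i) if (col[i] > mx) mx = col[i];
    for (int i = 1; i < n; ++i) if (col[i] < mn) mn = col[i];
    d2sum[j] = acc; maxL[j] = mx; minAll[j] = mn;
  }
  return List::create(_["d2sum"] = d2sum, _["max_l"] = maxL,
                      _["min_all"] = minAll);
}

// Column maxima over the first L rows (CBF extraction).
// [[Rcpp::export(name = ".col_max_l")]]
NumericVector col_max_l(const NumericMatrix& R, const int L) {
  const int p = R.ncol();
  if (L < 1 || L > R.nrow()) stop("invalid L");
  NumericVector out(p);
  for (int j = 0; j < p; ++j) {
    const double* col = &R(0, j);
    double mx = col[0];
    for (int i = 1; i < L; ++i) if (col[i] > mx) mx = col[i];
    out[j] = mx;
  }
  return out;
}
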