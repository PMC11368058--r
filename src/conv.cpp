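// im2col / col2im kernels for the conv-net engine. The surrounding
// bookkeeping (index tables, BLAS matmul, layer logic) stays in R; these
// two gather/scatter loops dominate runtime and are the only part worth
// compiling.

#include <Rcpp.h>
using namespace Rcpp;

// Gather the im2col matrix for a whole batch.
// xpv: padded input as a flat vector, sample plane length planeLen.
// idx: 1-based gather indices, dim (kRows x nCols) for one sample.
// [[Rcpp::export(name = ".cppIm2col")]]
NumericMatrix cppIm2col(NumericVector xpv, IntegerMatrix idx,
                        int planeLen, int N) {
  const int kRows = idx.nrow();
  const int nCols = idx.ncol();
  NumericMatrix out(kRows, nCols * N);
  const double* x = xpv.begin();
  const int* ip = idx.begin();
  double* o = out.begin();
  for (int n = 0; n < N; ++n) {
    const double* xn = x + (size_t)n * planeLen;
    double* on = o + (size_t)n * nCols * kRows;
    const size_t total = (size_t)nCols * kRows;
    for (size_t t = 0; t < total; ++t) on[t] = xn[ip[t] - 1];
  }
  return out;
}

// Scatter-add the column gradients back onto the padded input.
// [[Rcpp::export(name = ".cppCol2im")]]
NumericVector cppCol2im(NumericMatrix dXcol, IntegerMatrix idx,
                        int planeLen, int N) {
  const int kRows = idx.nrow();
  const int nCols = idx.ncol();
  NumericVector out((size_t)planeLen * N);
  double* o = out.begin();
  const double* d = dXcol.begin();
  const int* ip = idx.begin();
  for (int n = 0; n < N; ++n) {
    double* on = o + (size_t)n * planeLen;
    const double* dn = d + (size_t)n * nCols * kRows;
    const size_t total = (size_t)nCols * kRows;
    for (size_t t = 0; t < total; ++t) on[ip[t] - 1] += dn[t];
  }
  return out;
}
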