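// Hot inner loops of the convolution / pooling primitives: im2col gathers,
// col2im scatter-adds and max-pool argmax bookkeeping. Index tables are
// precomputed in R (1-based); matrix products stay in BLAS on the R side.
#include <Rcpp.h>
using namespace Rcpp;

// pad a flattened batch (in_len x N) into a padded buffer (L x N) at the
// positions fill_idx (1-based), remaining entries = fill value
// [[Rcpp::export]]
NumericMatrix cpp_pad_batch(const NumericMatrix& x, const IntegerVector& fill_idx,
                            int L, double fill) {
  const int n = x.ncol(), m = x.nrow();
  NumericMatrix pv(L, n);
  if (fill != 0.0) std::fill(pv.begin(), pv.end(), fill);
  for (int j = 0; j < n; ++j) {
    const double* xc = &x(0, j);
    double* pc = &pv(0, j);
    for (int i = 0; i < m; ++i) pc[fill_idx[i] - 1] = xc[i];
  }
  return pv;
}

// gather patches: returns (N*P) x K, rows image-major (row (n-1)*P + p)
// [[Rcpp::export]]
NumericMatrix cpp_im2col(const NumericMatrix& pv, const IntegerMatrix& idx) {
  const int P = idx.nrow(), K = idx.ncol(), n = pv.ncol();
  NumericMatrix cols((R_xlen_t)n * P, K);
  for (int k = 0; k < K; ++k) {
    const int* ic = &idx(0, k);
    double* cc = &cols(0, k);
    for (int j = 0; j < n; ++j) {
      const double* pc = &pv(0, j);
      double* out = cc + (R_xlen_t)j * P;
      for (int p = 0; p < P; ++p) out[p] = pc[ic[p] - 1];
    }
  }
  return cols;
}

// scatter-add patch values back onto the padded buffer (L x N)
// [[Rcpp::export]]
NumericMatrix cpp_col2im(const NumericMatrix& dcols, const IntegerMatrix& idx,
                         int L, int n) {
  const int P = idx.nrow(), K = idx.ncol();
  NumericMatrix dpad(L, n);
  for (int k = 0; k < K; ++k) {
    const int* ic = &idx(0, k);
    const double* dc = &dcols(0, k);
    for (int j = 0; j < n; ++j) {
      double* pc = &dpad(0, j);
      const double* in = dc + (R_xlen_t)j * P;
      for (int p = 0; p < P; ++p) pc[ic[p] - 1] += in[p];
    }
  }
  return dpad;
}

// strip padding: gather rows fill_idx from (L x N) into (in_len x N)
// [[Rcpp::export]]
NumericMatrix cpp_unpad_batch(const NumericMatrix& pv, const IntegerVector& fill_idx) {
  const int n = pv.ncol(), m = fill_idx.size();
  NumericMatrix x(m, n);
  for (int j = 0; j < n; ++j) {
    const double* pc = &pv(0, j);
    double* xc = &x(0, j);
    for (int i = 0; i < m; ++i) xc[i] = pc[fill_idx[i] - 1];
  }
  return x;
}

// max pooling over a padded single-channel-geometry buffer pv (L x CN):
// returns the max value and the winning patch element per output position
// [[Rcpp::export]]
List cpp_pool_forward(const NumericMatrix& pv, const IntegerMatrix& idx) {
  const int P = idx.nrow(), K = idx.ncol(), cn = pv.ncol();
  NumericMatrix best(P, cn);
  IntegerMatrix argk(P, cn);
  for (int j = 0; j < cn; ++j) {
    const double* pc = &pv(0, j);
    double* bc = &best(0, j);
    int* ac = &argk(0, j);
    for (int p = 0; p < P; ++p) {
      double b = pc[idx(p, 0) - 1];
      int a = 1;
      for (int k = 1; k < K; ++k) {
        double v = pc[idx(p, k) - 1];
        if (v > b) { b = v; a = k + 1; }
      }
      bc[p] = b;
      ac[p] = a;
    }
  }
  return List::create(_["best"] = best, _["argk"] = argk);
}

// route pooled values back to their argmax inputs (winner-take-all),
// accumulating where pooling windows overlap
// [[Rcpp::export]]
NumericMatrix cpp_pool_backward(const NumericMatrix& dout, const IntegerMatrix& argk,
                                const IntegerMatrix& idx, int L) {
  const int P = idx.nrow(), cn = dout.ncol();
  NumericMatrix dpad(L, cn);
  for (int j = 0; j < cn; ++j) {
    const double* dc = &dout(0, j);
    const int* ac = &argk(0, j);
    double* pc = &dpad(0, j);
    for (int p = 0; p < P; ++p) pc[idx(p, ac[p] - 1) - 1] += dc[p];
  }
  return dpad;
}
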