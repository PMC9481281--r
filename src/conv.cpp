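// Compiled hot path of the dilated causal convolution: im2col gather, the
// BLAS products, and the scatter-add fold of the backward pass. The index
// vector comes from R (memoized per layer shape); value T*B+1 marks the
// zero padding outside each beat's start. Outputs are allocated as R
// matrices and wrapped in Armadillo views, so nothing is copied on return.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// [[Rcpp::export]]
List cpp_conv_fwd(const arma::mat& X, const IntegerVector& idx, int k,
                  const arma::mat& Wm, const arma::vec& bias,
                  bool return_cols) {
  const arma::uword n = X.n_rows, cin = X.n_cols;
  const arma::uword cout = Wm.n_cols;

  NumericMatrix Xcol_r;
  arma::mat Xcol_view;
  const arma::mat* Xcol = &X;
  if (k > 1) {
    Xcol_r = NumericMatrix((int)n, (int)(k * cin));
    Xcol_view = arma::mat(Xcol_r.begin(), n, (arma::uword)k * cin, false,
                          true);
    for (int j = 0; j < k; ++j) {
      const int* src = &idx[(R_xlen_t)j * n];
      for (arma::uword c = 0; c < cin; ++c) {
        const double* xc = X.colptr(c);
        double* out = Xcol_view.colptr((arma::uword)j + c * (arma::uword)k);
        for (arma::uword r = 0; r < n; ++r) {
          const int s = src[r];
          out[r] = (s > (int)n) ? 0.0 : xc[s - 1];
        }
      }
    }
    Xcol = &Xcol_view;
  }

  NumericMatrix Y_r((int)n, (int)cout);
  arma::mat Y(Y_r.begin(), n, cout, false, true);
  Y = (*Xcol) * Wm;
  if (bias.n_elem > 0) Y.each_row() += bias.t();

  if (return_cols && k > 1)
    return List::create(_["Y"] = Y_r, _["Xcol"] = Xcol_r);
  if (return_cols)
    return List::create(_["Y"] = Y_r, _["Xcol"] = X);
  return List::create(_["Y"] = Y_r);
}

// [[Rcpp::export]]
List cpp_conv_bwd(const arma::mat& dY, const arma::mat& Xcol,
                  const IntegerVector& idx, int k, int cin,
                  const arma::mat& Wm) {
  const arma::uword n = dY.n_rows;

  NumericMatrix dW_r((int)Xcol.n_cols, (int)dY.n_cols);
  arma::mat dW(dW_r.begin(), Xcol.n_cols, dY.n_cols, false, true);
  dW = Xcol.t() * dY;

  arma::mat dXcol = dY * Wm.t();

  NumericMatrix dX_r((int)n, cin);
  arma::mat dX(dX_r.begin(), n, (arma::uword)cin, false, true);
  if (k == 1) {
    dX = dXcol;
  } else {
    dX.zeros();
    for (int j = 0; j < k; ++j) {
      const int* src = &idx[(R_xlen_t)j * n];
      for (int c = 0; c < cin; ++c) {
        const double* gc = dXcol.colptr((arma::uword)j +
                                        (arma::uword)c * (arma::uword)k);
        double* out = dX.colptr(c);
        for (arma::uword r = 0; r < n; ++r) {
          const int s = src[r];
          if (s <= (int)n) out[s - 1] += gc[r];
        }
      }
    }
  }
  NumericVector db_r((int)dY.n_cols);
  arma::rowvec db(db_r.begin(), dY.n_cols, false, true);
  db = arma::sum(dY, 0);
  return List::create(_["dX"] = dX_r, _["dW"] = dW_r, _["db"] = db_r);
}

// Max pooling over non-overlapping windows of f time steps per beat
// (column-major activations, time fastest within beat). Returns pooled
// values and 1-based argmax row indices for the backward scatter.
// [[Rcpp::export]]
List cpp_maxpool_fwd(const arma::mat& X, int f, int T_len, int B) {
  const int T_out = T_len / f;
  const arma::uword n_out = (arma::uword)T_out * B, C = X.n_cols;
  NumericMatrix Y_r((int)n_out, (int)C);
  IntegerMatrix IDX_r((int)n_out, (int)C);
  for (arma::uword c = 0; c < C; ++c) {
    const double* xc = X.colptr(c);
    double* yc = &Y_r[(R_xlen_t)c * n_out];
    int* ic = &IDX_r[(R_xlen_t)c * n_out];
    arma::uword o = 0;
    for (int b = 0; b < B; ++b) {
      const double* beat = xc + (R_xlen_t)b * T_len;
      for (int t = 0; t < T_out; ++t, ++o) {
        const double* w = beat + (R_xlen_t)t * f;
        int best = 0;
        double v = w[0];
        for (int u = 1; u < f; ++u)
          if (w[u] > v) { v = w[u]; best = u; }
        yc[o] = v;
        ic[o] = b * T_len + t * f + best + 1;
      }
    }
  }
  return List::create(_["Y"] = Y_r, _["IDX"] = IDX_r);
}

// [[Rcpp::export]]
NumericMatrix cpp_maxpool_bwd(const arma::mat& dY, const IntegerMatrix& IDX,
                              int T_len, int B) {
  const arma::uword C = dY.n_cols, n_out = dY.n_rows;
  NumericMatrix dX_r(T_len * B, (int)C);
  for (arma::uword c = 0; c < C; ++c) {
    const double* gc = dY.colptr(c);
    const int* ic = &IDX[(R_xlen_t)c * n_out];
    double* out = &dX_r[(R_xlen_t)c * T_len * B];
    for (arma::uword r = 0; r < n_out; ++r)
      out[ic[r] - 1] += gc[r];
  }
  return dX_r;
}
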