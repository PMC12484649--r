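// Dilated causal 1-D convolution kernels for the waveform encoder.
// The tap loop over BLAS GEMMs is the hot path of training; implemented in
// C++ to avoid per-tap slice copies in R. Tap j (0-based) reads the input at
// lag (k - 1 - j) * d, so output sample t depends only on inputs <= t
// (causality by construction; the left zero pad is implicit).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export]]
arma::mat conv_causal_fwd_cpp(const arma::mat& X, const arma::cube& W,
                              const arma::vec& b, const int d) {
  const int k = W.n_slices;
  const int T = X.n_cols;
  mat Y(W.n_rows, T);
  Y.each_col() = b;
  for (int j = 0; j < k; ++j) {
    const int off = (k - 1 - j) * d;
    if (off >= T) continue;
    Y.cols(off, T - 1) += W.slice(j) * X.cols(0, T - 1 - off);
  }
  return Y;
}

// [[Rcpp::export]]
Rcpp::List conv_causal_bwd_cpp(const arma::mat& dY, const arma::mat& X,
                               const arma::cube& W, const int d) {
  const int k = W.n_slices;
  const int T = X.n_cols;
  mat dX(X.n_rows, T, fill::zeros);
  cube dW(W.n_rows, W.n_cols, k, fill::zeros);
  vec db = sum(dY, 1);
  for (int j = 0; j < k; ++j) {
    const int off = (k - 1 - j) * d;
    if (off >= T) continue;
    dW.slice(j) = dY.cols(off, T - 1) * X.cols(0, T - 1 - off).t();
    dX.cols(0, T - 1 - off) += W.slice(j).t() * dY.cols(off, T - 1);
  }
  return Rcpp::List::create(Rcpp::Named("dX") = dX,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}
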