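// Compiled kernels for the 3x3 convolutions of the encoder-decoder network.
// A convolution is a zero-padded patch gather followed by one GEMM; the
// input gradient is a gather-convolution with the flipped kernel, so no
// scatter is ever needed. Layouts match the R reference implementation:
// feature matrices are (pixels*batch) x channels, weight rows are ordered
// taps-fastest within input channel, and `idx` is the tap-major source-row
// index with n_rows + 1 the zero-padding sentinel. The patch matrix stays
// on this side of the R/C++ boundary; the backward pass re-gathers it from
// the (much smaller) cached layer input.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::mat gather_patches(const arma::mat& X, const IntegerVector& idx) {
  const arma::uword n = X.n_rows, cin = X.n_cols;
  arma::mat G(n, 9 * cin, arma::fill::none);
  for (arma::uword c = 0; c < cin; ++c) {
    const double* xc = X.colptr(c);
    for (arma::uword k = 0; k < 9; ++k) {
      double* g = G.colptr(c * 9 + k);
      const int* id = &idx[k * n];
      for (arma::uword i = 0; i < n; ++i) {
        const int s = id[i];
        g[i] = (s <= (int)n) ? xc[s - 1] : 0.0;
      }
    }
  }
  return G;
}

// [[Rcpp::export]]
arma::mat conv_fwd_cpp(const arma::mat& X, const arma::mat& W,
                       const arma::vec& b, const IntegerVector& idx) {
  arma::mat Y = gather_patches(X, idx) * W;
  Y.each_row() += b.t();
  return Y;
}

// [[Rcpp::export]]
List conv_bwd_cpp(const arma::mat& dY, const arma::mat& X, const arma::mat& W,
                  const IntegerVector& idx) {
  const arma::uword cin = X.n_cols, cout = W.n_cols;
  arma::mat dW = gather_patches(X, idx).t() * dY;
  arma::vec db = arma::sum(dY, 0).t();
  arma::mat Wb(9 * cout, cin, arma::fill::none);
  for (arma::uword c = 0; c < cin; ++c)
    for (arma::uword o = 0; o < cout; ++o)
      for (arma::uword k = 0; k < 9; ++k)
        Wb(o * 9 + k, c) = W(c * 9 + (8 - k), o);
  arma::mat dX = gather_patches(dY, idx) * Wb;
  return List::create(_["dW"] = dW, _["db"] = db, _["dX"] = dX);
}
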