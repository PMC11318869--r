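// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;

// Causal dilated 1-D convolution kernels used by the TCN layers.
// Tensors are column-major cubes: x [c_in x T x B], W [c_out x c_in x k],
// output [c_out x T x B]. Tap j (1-based) reads the input delayed by
// (k - j) * dilation steps with implicit left zero padding, so the output
// at time t depends on inputs at times <= t only.

// [[Rcpp::export(name = ".conv1d_fwd")]]
arma::cube conv1d_fwd(const arma::cube& W, const arma::vec& b,
                      const arma::cube& x, const int dilation) {
  const int c_out = W.n_rows, c_in = W.n_cols, k = W.n_slices;
  const int T = x.n_cols, B = x.n_slices;
  const int pad = (k - 1) * dilation;
  if ((int)x.n_rows != c_in) stop("channel mismatch in conv1d");

  arma::cube out(c_out, T, B);
  arma::mat xp(c_in, T + pad, arma::fill::zeros);
  for (int bb = 0; bb < B; ++bb) {
    xp.cols(pad, pad + T - 1) = x.slice(bb);
    arma::mat& o = out.slice(bb);
    o = arma::repmat(b, 1, T);
    for (int j = 0; j < k; ++j) {
      const int start = j * dilation;
      o += W.slice(j) * xp.cols(start, start + T - 1);
    }
  }
  return out;
}

// [[Rcpp::export(name = ".conv1d_bwd")]]
List conv1d_bwd(const arma::cube& W, const arma::cube& x,
                const arma::cube& dout, const int dilation) {
  const int c_out = W.n_rows, c_in = W.n_cols, k = W.n_slices;
  const int T = x.n_cols, B = x.n_slices;
  const int pad = (k - 1) * dilation;

  arma::cube dW(c_out, c_in, k, arma::fill::zeros);
  arma::vec db(c_out, arma::fill::zeros);
  arma::cube dx(c_in, T, B);
  arma::mat xp(c_in, T + pad, arma::fill::zeros);
  arma::mat dxp(c_in, T + pad);
  for (int bb = 0; bb < B; ++bb) {
    xp.cols(pad, pad + T - 1) = x.slice(bb);
    dxp.zeros();
    const arma::mat& do_ = dout.slice(bb);
    db += arma::sum(do_, 1);
    for (int j = 0; j < k; ++j) {
      const int start = j * dilation;
      dW.slice(j) += do_ * xp.cols(start, start + T - 1).t();
      dxp.cols(start, start + T - 1) += W.slice(j).t() * do_;
    }
    dx.slice(bb) = dxp.cols(pad, pad + T - 1);
  }
  return List::create(_["dW"] = dW, _["db"] = db, _["dx"] = dx);
}
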