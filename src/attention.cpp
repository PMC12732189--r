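// Scaled dot-product multi-head attention kernels.
// The quadratic attention maps dominate training time, so the per-head
// forward and backward passes run in compiled code; the R-level per-head
// loop in the test suite serves as the independent reference.
//
// Layout note: attention is computed and cached TRANSPOSED (St = K Q^T, so
// scores for one query occupy one contiguous column). All softmax
// reductions are then column-wise, which is cache-friendly for Armadillo's
// column-major storage. `attn_t[[i]]` is column-stochastic; transpose to
// obtain the usual row-stochastic attention matrix.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static void softmax_cols_inplace(arma::mat& s) {
  arma::rowvec m = arma::max(s, 0);
  s.each_row() -= m;
  s = arma::exp(s);
  arma::rowvec z = arma::sum(s, 0);
  s.each_row() /= z;
}

// Q, K, V: (N+1) x D. Returns the concatenated head outputs and the
// per-head transposed (column-stochastic) attention matrices.
// [[Rcpp::export]]
List attention_forward_cpp(const arma::mat& Q, const arma::mat& K,
                           const arma::mat& V, const int h) {
  const int D = Q.n_cols;
  const int Dh = D / h;
  const double scale = 1.0 / std::sqrt((double)Dh);
  arma::mat Hcat(Q.n_rows, D);
  List attn_t(h);
  for (int i = 0; i < h; ++i) {
    arma::span idx(i * Dh, (i + 1) * Dh - 1);
    arma::mat St = K.cols(idx) * Q.cols(idx).t() * scale;
    if (!St.is_finite()) stop("non-finite attention logits");
    softmax_cols_inplace(St);
    Hcat.cols(idx) = St.t() * V.cols(idx);
    attn_t[i] = St;
  }
  return List::create(_["Hcat"] = Hcat, _["attn_t"] = attn_t);
}

// Gradients of the attention block inputs given the gradient of the
// concatenated head outputs and the cached transposed attention.
// [[Rcpp::export]]
List attention_backward_cpp(const arma::mat& dHcat, const arma::mat& Q,
                            const arma::mat& K, const arma::mat& V,
                            const List& attn_t) {
  const int D = Q.n_cols;
  const int h = attn_t.size();
  const int Dh = D / h;
  const double scale = 1.0 / std::sqrt((double)Dh);
  arma::mat dQ(Q.n_rows, D, arma::fill::zeros);
  arma::mat dK(Q.n_rows, D, arma::fill::zeros);
  arma::mat dV(Q.n_rows, D, arma::fill::zeros);
  for (int i = 0; i < h; ++i) {
    arma::span idx(i * Dh, (i + 1) * Dh - 1);
    const arma::mat At = as<arma::mat>(attn_t[i]);  // (keys x queries)
    arma::mat dHi = dHcat.cols(idx);
    // dA^T = V dH^T ; column j holds d(attention of query j)
    arma::mat dAt = V.cols(idx) * dHi.t();
    dV.cols(idx) = At * dHi;
    // softmax backward per query (= per column in transposed layout)
    arma::rowvec rs = arma::sum(dAt % At, 0);
    arma::mat dSt = At % (dAt.each_row() - rs);
    dQ.cols(idx) = dSt.t() * K.cols(idx) * scale;
    dK.cols(idx) = dSt * Q.cols(idx) * scale;
  }
  return List::create(_["dQ"] = dQ, _["dK"] = dK, _["dV"] = dV);
}
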