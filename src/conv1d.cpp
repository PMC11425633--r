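// Batched 1-D convolution (stride 1, zero "same"-style padding) used by the
// CNN front-end.  Activations are C x (B*T) matrices with each sample's T
// time steps contiguous; weights are Cout x (Cin*k) with columns ordered
// offset-major (column j*Cin + c = tap j, input channel c).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

static mat pad_batch(const mat& X, int B, int T, int k, int pad_l) {
  int Tp = T + k - 1;
  mat Xp(X.n_rows, (uword)B * Tp, fill::zeros);
  for (int b = 0; b < B; ++b)
    Xp.cols((uword)b * Tp + pad_l, (uword)b * Tp + pad_l + T - 1) =
        X.cols((uword)b * T, (uword)(b + 1) * T - 1);
  return Xp;
}

static mat im2col(const mat& Xp, int B, int T, int k) {
  int Cin = Xp.n_rows, Tp = T + k - 1;
  mat XC((uword)Cin * k, (uword)B * T);
  for (int j = 0; j < k; ++j)
    for (int b = 0; b < B; ++b)
      XC.submat((uword)j * Cin, (uword)b * T, (uword)(j + 1) * Cin - 1,
                (uword)(b + 1) * T - 1) =
          Xp.cols((uword)b * Tp + j, (uword)b * Tp + j + T - 1);
  return XC;
}

// [[Rcpp::export]]
Rcpp::List conv1d_fwd(const arma::mat& X, int B, int T, const arma::mat& W,
                      const arma::vec& bias, int k, int pad_l,
                      bool keep_cols) {
  mat Xp = pad_batch(X, B, T, k, pad_l);
  mat XC = im2col(Xp, B, T, k);
  mat Y = W * XC;
  Y.each_col() += bias;
  if (keep_cols)
    return Rcpp::List::create(Rcpp::Named("Y") = Y,
                              Rcpp::Named("XC") = XC);
  return Rcpp::List::create(Rcpp::Named("Y") = Y);
}

// reuses the forward pass's im2col matrix; only the input-gradient
// scatter needs the padded geometry
// [[Rcpp::export]]
Rcpp::List conv1d_bwd(const arma::mat& XC, const arma::mat& dY, int B,
                      int T, const arma::mat& W, int k, int pad_l) {
  int Cin = (int)W.n_cols / k, Tp = T + k - 1;
  mat dW = dY * XC.t();
  vec db = sum(dY, 1);
  mat G = W.t() * dY;  // (Cin*k) x (B*T)
  mat dXp(Cin, (uword)B * Tp, fill::zeros);
  for (int j = 0; j < k; ++j)
    for (int b = 0; b < B; ++b)
      dXp.cols((uword)b * Tp + j, (uword)b * Tp + j + T - 1) +=
          G.submat((uword)j * Cin, (uword)b * T, (uword)(j + 1) * Cin - 1,
                   (uword)(b + 1) * T - 1);
  mat dX(Cin, (uword)B * T);
  for (int b = 0; b < B; ++b)
    dX.cols((uword)b * T, (uword)(b + 1) * T - 1) =
        dXp.cols((uword)b * Tp + pad_l, (uword)b * Tp + pad_l + T - 1);
  return Rcpp::List::create(Rcpp::Named("dX") = dX, Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}
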