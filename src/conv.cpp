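// Valid stride-1 1-D convolution kernels on the flattened (B*n, m) window
// layout (row index = sample + position*B). Each kernel tap j contributes a
// contiguous row block of X %*% W_j, so forward and backward are plain GEMMs
// over submatrix views with no intermediate gather/scatter buffers.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export(name = ".conv_fwd_cpp")]]
arma::mat conv_fwd_cpp(const arma::mat& X, const arma::mat& W,
                       const arma::vec& b, int k, int B) {
  const int n = X.n_rows / B;
  const int m = X.n_cols;
  const int on = n - k + 1;
  const int rows = B * on;
  mat Z(rows, W.n_cols);
  Z.each_row() = b.t();
  for (int j = 0; j < k; ++j) {
    Z += X.rows(j * B, j * B + rows - 1) * W.rows(j * m, (j + 1) * m - 1);
  }
  return Z;
}

// [[Rcpp::export(name = ".relu_cpp")]]
arma::mat relu_cpp(const arma::mat& Z) {
  return clamp(Z, 0.0, datum::inf);
}

// [[Rcpp::export(name = ".relu_bwd_cpp")]]
arma::mat relu_bwd_cpp(const arma::mat& dA, const arma::mat& A) {
  return dA % (A > 0);
}

// layer normalization over the feature axis, per sample (row)
// [[Rcpp::export(name = ".ln_fwd_cpp")]]
Rcpp::List ln_fwd_cpp(const arma::mat& X, const arma::vec& gamma,
                      const arma::vec& beta, double eps) {
  vec mu = mean(X, 1);
  mat xc = X.each_col() - mu;
  vec v = mean(square(xc), 1);
  vec inv = 1.0 / sqrt(v + eps);
  mat xhat = xc.each_col() % inv;
  mat Y = (xhat.each_row() % gamma.t()).each_row() + beta.t();
  return Rcpp::List::create(Rcpp::Named("Y") = Y,
                            Rcpp::Named("xhat") = xhat,
                            Rcpp::Named("inv") = inv);
}

// [[Rcpp::export(name = ".ln_bwd_cpp")]]
Rcpp::List ln_bwd_cpp(const arma::mat& dY, const arma::mat& xhat,
                      const arma::vec& inv, const arma::vec& gamma) {
  rowvec dgamma = sum(dY % xhat, 0);
  rowvec dbeta = sum(dY, 0);
  mat dxhat = dY.each_row() % gamma.t();
  vec m1 = mean(dxhat, 1);
  vec m2 = mean(dxhat % xhat, 1);
  mat dX = dxhat;
  dX.each_col() -= m1;
  dX -= xhat.each_col() % m2;
  dX.each_col() %= inv;
  return Rcpp::List::create(
    Rcpp::Named("dX") = dX,
    Rcpp::Named("dgamma") = Rcpp::NumericVector(dgamma.begin(), dgamma.end()),
    Rcpp::Named("dbeta") = Rcpp::NumericVector(dbeta.begin(), dbeta.end()));
}

// [[Rcpp::export(name = ".conv_bwd_cpp")]]
Rcpp::List conv_bwd_cpp(const arma::mat& dZ, const arma::mat& X,
                        const arma::mat& W, int k, int B, bool need_dX) {
  const int n = X.n_rows / B;
  const int m = X.n_cols;
  const int on = n - k + 1;
  const int rows = B * on;
  mat dW(k * m, W.n_cols);
  for (int j = 0; j < k; ++j) {
    dW.rows(j * m, (j + 1) * m - 1) =
      X.rows(j * B, j * B + rows - 1).t() * dZ;
  }
  rowvec db = sum(dZ, 0);
  Rcpp::List out = Rcpp::List::create(
    Rcpp::Named("dW") = dW,
    Rcpp::Named("db") = Rcpp::NumericVector(db.begin(), db.end()));
  if (need_dX) {
    mat dX(B * n, m, fill::zeros);
    for (int j = 0; j < k; ++j) {
      dX.rows(j * B, j * B + rows - 1) +=
        dZ * W.rows(j * m, (j + 1) * m - 1).t();
    }
    out["dXmat"] = dX;
  }
  return out;
}
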