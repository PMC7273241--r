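// Same-padded 1-D convolution over batched sequences.
//
// Activations are stored as (L*B) x C matrices: time fastest within each
// batch block of L rows. Each kernel offset contributes one matrix product
// per batch block over the valid time range, so no padded/gathered copies
// of the activations are ever materialized.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using arma::mat;
using arma::vec;

// A: (L*B) x Cin; W: (k*Cin) x Cout (rows j*Cin..(j+1)*Cin-1 hold the
// weights for kernel offset j, source time t + j - pad); b: Cout.
// [[Rcpp::export]]
arma::mat conv1d_fwd(const arma::mat& A, const arma::mat& W,
                     const arma::vec& b, int L, int B, int k) {
  const int Cin = A.n_cols;
  const int Cout = W.n_cols;
  const int pad = (k - 1) / 2;
  mat Y(static_cast<arma::uword>(L) * B, Cout, arma::fill::zeros);
  for (int j = 0; j < k; ++j) {
    const int d = j - pad;
    const int t0 = std::max(0, -d);
    const int t1 = std::min(L - 1, L - 1 - d);
    if (t0 > t1) continue;
    const mat Wj = W.rows(j * Cin, (j + 1) * Cin - 1);
    for (int bb = 0; bb < B; ++bb) {
      const int base = bb * L;
      Y.rows(base + t0, base + t1) +=
        A.rows(base + t0 + d, base + t1 + d) * Wj;
    }
  }
  Y.each_row() += b.t();
  return Y;
}

// Gradients of the same convolution. dY: (L*B) x Cout.
// [[Rcpp::export]]
Rcpp::List conv1d_bwd(const arma::mat& A, const arma::mat& W,
                      const arma::mat& dY, int L, int B, int k) {
  const int Cin = A.n_cols;
  const int pad = (k - 1) / 2;
  mat dW(arma::size(W), arma::fill::zeros);
  mat dA(arma::size(A), arma::fill::zeros);
  for (int j = 0; j < k; ++j) {
    const int d = j - pad;
    const int t0 = std::max(0, -d);
    const int t1 = std::min(L - 1, L - 1 - d);
    if (t0 > t1) continue;
    const mat Wj = W.rows(j * Cin, (j + 1) * Cin - 1);
    mat dWj(Cin, W.n_cols, arma::fill::zeros);
    for (int bb = 0; bb < B; ++bb) {
      const int base = bb * L;
      dWj += A.rows(base + t0 + d, base + t1 + d).t() *
             dY.rows(base + t0, base + t1);
      dA.rows(base + t0 + d, base + t1 + d) +=
        dY.rows(base + t0, base + t1) * Wj.t();
    }
    dW.rows(j * Cin, (j + 1) * Cin - 1) = dWj;
  }
  const vec db = arma::sum(dY, 0).t();
  return Rcpp::List::create(Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db,
                            Rcpp::Named("dA") = dA);
}

// Batch normalization over rows, per channel column.
// training: use batch statistics (returned for the running averages);
// otherwise normalize with the supplied running statistics.
// [[Rcpp::export]]
Rcpp::List bn_fwd_cpp(const arma::mat& Y, const arma::vec& gamma,
                      const arma::vec& beta, bool training,
                      const arma::vec& run_mean, const arma::vec& run_var) {
  const double eps = 1e-5;
  const arma::uword N = Y.n_rows, C = Y.n_cols;
  arma::vec mu(C), vr(C);
  if (training) {
    for (arma::uword c = 0; c < C; ++c) {
      mu[c] = arma::mean(Y.col(c));
      vr[c] = arma::mean(arma::square(Y.col(c))) - mu[c] * mu[c];
    }
  } else {
    mu = run_mean;
    vr = run_var;
  }
  mat xhat(N, C), out(N, C);
  vec inv_std(C);
  for (arma::uword c = 0; c < C; ++c) {
    inv_std[c] = 1.0 / std::sqrt(vr[c] + eps);
    xhat.col(c) = (Y.col(c) - mu[c]) * inv_std[c];
    out.col(c) = xhat.col(c) * gamma[c] + beta[c];
  }
  return Rcpp::List::create(Rcpp::Named("out") = out,
                            Rcpp::Named("xhat") = xhat,
                            Rcpp::Named("inv_std") = inv_std,
                            Rcpp::Named("mu") = mu,
                            Rcpp::Named("vr") = vr);
}

// [[Rcpp::export]]
Rcpp::List bn_bwd_cpp(const arma::mat& dOut, const arma::mat& xhat,
                      const arma::vec& inv_std, const arma::vec& gamma) {
  const arma::uword N = dOut.n_rows, C = dOut.n_cols;
  vec dgamma(C), dbeta(C);
  mat dY(N, C);
  for (arma::uword c = 0; c < C; ++c) {
    dgamma[c] = arma::dot(dOut.col(c), xhat.col(c));
    dbeta[c] = arma::accu(dOut.col(c));
    const double g_inv = gamma[c] * inv_std[c];
    dY.col(c) = (dOut.col(c) - dbeta[c] / N - xhat.col(c) * (dgamma[c] / N)) * g_inv;
  }
  return Rcpp::List::create(Rcpp::Named("dY") = dY,
                            Rcpp::Named("dgamma") = dgamma,
                            Rcpp::Named("dbeta") = dbeta);
}
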