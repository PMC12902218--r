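// Low-level kernels for the 1-D CNN: same-padded convolution and max-pooling,
// forward and backward, over batches stored as cubes (length x channels x batch).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static mat weight_matrix(const cube& W) {
  // W is kernel x Cin x Cout; column co holds vectorise(W.slice(co)),
  // column-major so entry (j + k*ci) multiplies X(l + j - pad, ci)
  const uword k = W.n_rows, Cin = W.n_cols, Cout = W.n_slices;
  mat Wmat(k * Cin, Cout);
  for (uword co = 0; co < Cout; ++co) Wmat.col(co) = vectorise(W.slice(co));
  return Wmat;
}

static void fill_patches(mat& P, const mat& Xn, uword L, uword Cin, uword k, uword pad) {
  P.zeros();
  for (uword ci = 0; ci < Cin; ++ci) {
    for (uword j = 0; j < k; ++j) {
      const long lo = (long)pad - (long)j;  // output row l reads input row l - lo
      const long lstart = std::max((long)0, lo);
      const long lend = std::min((long)L - 1, (long)L - 1 + lo);
      if (lend < lstart) continue;
      P.col(j + k * ci).rows(lstart, lend) = Xn.col(ci).rows(lstart - lo, lend - lo);
    }
  }
}

// [[Rcpp::export]]
arma::cube conv1d_fwd(const arma::cube& X, const arma::cube& W, const arma::vec& b) {
  const uword L = X.n_rows, Cin = X.n_cols, N = X.n_slices;
  const uword k = W.n_rows, Cout = W.n_slices;
  if (W.n_cols != Cin) Rcpp::stop("conv1d_fwd: channel mismatch");
  const uword pad = (k - 1) / 2;
  const mat Wmat = weight_matrix(W);
  cube Y(L, Cout, N);
  mat P(L, k * Cin);
  for (uword n = 0; n < N; ++n) {
    fill_patches(P, X.slice(n), L, Cin, k, pad);
    Y.slice(n) = P * Wmat;
    Y.slice(n).each_row() += b.t();
  }
  return Y;
}

// [[Rcpp::export]]
Rcpp::List conv1d_bwd(const arma::cube& X, const arma::cube& W, const arma::cube& dY) {
  const uword L = X.n_rows, Cin = X.n_cols, N = X.n_slices;
  const uword k = W.n_rows, Cout = W.n_slices;
  const uword pad = (k - 1) / 2;
  const mat Wmat = weight_matrix(W);
  cube dX(L, Cin, N, fill::zeros);
  mat dWmat(k * Cin, Cout, fill::zeros);
  vec db(Cout, fill::zeros);
  mat P(L, k * Cin);
  for (uword n = 0; n < N; ++n) {
    fill_patches(P, X.slice(n), L, Cin, k, pad);
    const mat& dYn = dY.slice(n);
    dWmat += P.t() * dYn;
    db += sum(dYn, 0).t();
    const mat dP = dYn * Wmat.t();
    for (uword ci = 0; ci < Cin; ++ci) {
      for (uword j = 0; j < k; ++j) {
        const long lo = (long)pad - (long)j;
        const long lstart = std::max((long)0, lo);
        const long lend = std::min((long)L - 1, (long)L - 1 + lo);
        if (lend < lstart) continue;
        dX.slice(n).col(ci).rows(lstart - lo, lend - lo) +=
          dP.col(j + k * ci).rows(lstart, lend);
      }
    }
  }
  cube dW(k, Cin, Cout);
  for (uword co = 0; co < Cout; ++co)
    dW.slice(co) = reshape(dWmat.col(co), k, Cin);
  return Rcpp::List::create(Rcpp::Named("dX") = dX,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

// [[Rcpp::export]]
Rcpp::List maxpool_fwd(const arma::cube& X, const int pool) {
  const uword L = X.n_rows, C = X.n_cols, N = X.n_slices;
  if (pool < 1 || L % pool != 0) Rcpp::stop("maxpool_fwd: length not divisible by pool");
  const uword Lout = L / pool;
  cube Y(Lout, C, N);
  cube idx(Lout, C, N);  // absolute input row of each max, stored as double
  for (uword n = 0; n < N; ++n) {
    for (uword c = 0; c < C; ++c) {
      for (uword l = 0; l < Lout; ++l) {
        uword best = l * pool;
        double bv = X(best, c, n);
        for (uword j = 1; j < (uword)pool; ++j) {
          const double v = X(l * pool + j, c, n);
          if (v > bv) { bv = v; best = l * pool + j; }
        }
        Y(l, c, n) = bv;
        idx(l, c, n) = (double)best;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("Y") = Y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export]]
arma::cube maxpool_bwd(const arma::cube& dY, const arma::cube& idx, const int Lin) {
  const uword Lout = dY.n_rows, C = dY.n_cols, N = dY.n_slices;
  cube dX(Lin, C, N, fill::zeros);
  for (uword n = 0; n < N; ++n)
    for (uword c = 0; c < C; ++c)
      for (uword l = 0; l < Lout; ++l)
        dX((uword)idx(l, c, n), c, n) += dY(l, c, n);
  return dX;
}
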