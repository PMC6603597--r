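// Kernel-3, stride-1, zero-pad-1 one-dimensional convolution lowered to a
// BLAS matrix product via im2col. Activations are (channels, length,
// batch) cubes. The im2col matrix is rebuilt in the backward pass instead
// of being cached, trading a cheap gather for a large memory saving.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static mat im2col3(const cube& X) {
  const uword C = X.n_rows, L = X.n_cols, N = X.n_slices;
  mat out(3 * C, L * N);
  for (uword n = 0; n < N; ++n) {
    const mat& s = X.slice(n);
    for (uword l = 0; l < L; ++l) {
      double* col = out.colptr(n * L + l);
      for (int j = 0; j < 3; ++j) {
        const long li = static_cast<long>(l) + j - 1;
        if (li < 0 || li >= static_cast<long>(L)) {
          std::fill(col + j * C, col + (j + 1) * C, 0.0);
        } else {
          std::memcpy(col + j * C, s.colptr(li), C * sizeof(double));
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
arma::cube cpp_conv_forward(const arma::cube& X, const arma::mat& W,
                            const arma::vec& b) {
  const uword L = X.n_cols, N = X.n_slices;
  mat Y = W * im2col3(X);
  Y.each_col() += b;
  return cube(Y.memptr(), W.n_rows, L, N);
}

// [[Rcpp::export]]
Rcpp::List cpp_conv_backward(const arma::cube& X, const arma::mat& W,
                             const arma::cube& dY) {
  const uword C = X.n_rows, L = X.n_cols, N = X.n_slices;
  const mat dYm(const_cast<double*>(dY.memptr()), dY.n_rows, L * N, false);
  const mat Xcol = im2col3(X);
  mat dW = dYm * Xcol.t();
  vec db = sum(dYm, 1);
  mat dXcol = W.t() * dYm;
  cube dX(C, L, N, fill::zeros);
  for (uword n = 0; n < N; ++n) {
    mat& s = dX.slice(n);
    for (uword l = 0; l < L; ++l) {
      const double* col = dXcol.colptr(n * L + l);
      for (int j = 0; j < 3; ++j) {
        const long li = static_cast<long>(l) + j - 1;
        if (li < 0 || li >= static_cast<long>(L)) continue;
        double* dst = s.colptr(li);
        const double* src = col + j * C;
        for (uword c = 0; c < C; ++c) dst[c] += src[c];
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db,
                            Rcpp::Named("dX") = dX);
}
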