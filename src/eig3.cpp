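#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Batch eigendecomposition of symmetric 3x3 tensors.
// d6: n x 6 matrix of components (xx, yy, zz, xy, xz, yz).
// Returns eigenvalues sorted descending and the matching eigenvectors
// (rows of `vectors` hold e1, e2, e3 concatenated).
// [[Rcpp::export]]
Rcpp::List eig3_batch(const arma::mat& d6) {
  const arma::uword n = d6.n_rows;
  arma::mat vals(n, 3);
  arma::mat vecs(n, 9);
  arma::mat33 D;
  arma::vec3 ev;
  arma::mat33 V;
  for (arma::uword i = 0; i < n; ++i) {
    D(0, 0) = d6(i, 0); D(1, 1) = d6(i, 1); D(2, 2) = d6(i, 2);
    D(0, 1) = D(1, 0) = d6(i, 3);
    D(0, 2) = D(2, 0) = d6(i, 4);
    D(1, 2) = D(2, 1) = d6(i, 5);
    arma::eig_sym(ev, V, D);   // ascending
    for (int k = 0; k < 3; ++k) {
      vals(i, k) = ev(2 - k);
      for (int c = 0; c < 3; ++c) vecs(i, 3 * k + c) = V(c, 2 - k);
    }
  }
  return Rcpp::List::create(Rcpp::Named("values") = vals,
                            Rcpp::Named("vectors") = vecs);
}
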