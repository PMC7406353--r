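#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Eigendecomposition of a field of symmetric 3x3 tensors.
// S: n x 6 matrix with columns xx, yy, zz, xy, xz, yz.
// Returns values (n x 3, descending) and vectors (n x 9; e1 in cols 1:3,
// e2 in 4:6, e3 in 7:9, each the eigenvector paired with the same-rank value).
// [[Rcpp::export]]
List eig3_field(const arma::mat& S) {
  const arma::uword n = S.n_rows;
  arma::mat vals(n, 3), vecs(n, 9);
  arma::mat33 A;
  arma::vec ev;
  arma::mat V;
  for (arma::uword i = 0; i < n; ++i) {
    A(0, 0) = S(i, 0); A(1, 1) = S(i, 1); A(2, 2) = S(i, 2);
    A(0, 1) = A(1, 0) = S(i, 3);
    A(0, 2) = A(2, 0) = S(i, 4);
    A(1, 2) = A(2, 1) = S(i, 5);
    arma::eig_sym(ev, V, A);  // ascending order
    vals(i, 0) = ev(2); vals(i, 1) = ev(1); vals(i, 2) = ev(0);
    for (int k = 0; k < 3; ++k) {
      vecs(i, k)     = V(k, 2);
      vecs(i, 3 + k) = V(k, 1);
      vecs(i, 6 + k) = V(k, 0);
    }
  }
  return List::create(_["values"] = vals, _["vectors"] = vecs);
}
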