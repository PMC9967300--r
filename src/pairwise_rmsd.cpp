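// Pairwise frame-frame RMSD over a fixed atom selection, optionally after
// optimal rigid superposition (Kabsch, via SVD of the 3x3 covariance).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// coords: n_atoms x 3 x n_frames cube (already restricted to the selection)
// [[Rcpp::export]]
arma::mat pairwise_rmsd_cpp(const arma::cube& coords, const bool superpose) {
  const arma::uword nf = coords.n_slices;
  const arma::uword na = coords.n_rows;
  arma::mat out(nf, nf, arma::fill::zeros);

  if (!superpose) {
    for (arma::uword i = 0; i < nf; ++i) {
      for (arma::uword j = i + 1; j < nf; ++j) {
        const double v = arma::accu(arma::square(coords.slice(i) - coords.slice(j))) / na;
        out(i, j) = out(j, i) = std::sqrt(v);
      }
    }
    return out;
  }

  // center every frame once; cache squared norms
  arma::cube X = coords;
  arma::vec E(nf);
  for (arma::uword k = 0; k < nf; ++k) {
    arma::mat Xi = X.slice(k);
    Xi.each_row() -= arma::mean(Xi, 0);
    X.slice(k) = Xi;
    E(k) = arma::accu(arma::square(Xi));
  }

  arma::mat U, V;
  arma::vec s;
  for (arma::uword i = 0; i < nf; ++i) {
    for (arma::uword j = i + 1; j < nf; ++j) {
      const arma::mat C = X.slice(i).t() * X.slice(j);
      if (!arma::svd(U, s, V, C)) Rcpp::stop("SVD failed in RMSD superposition");
      const double sign = (arma::det(U) * arma::det(V) < 0.0) ? -1.0 : 1.0;
      const double tr = s(0) + s(1) + sign * s(2);
      const double v = (E(i) + E(j) - 2.0 * tr) / na;
      out(i, j) = out(j, i) = std::sqrt(std::max(v, 0.0));
    }
  }
  return out;
}
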