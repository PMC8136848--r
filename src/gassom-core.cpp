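// Fused numerical cores of the GASSOM coder.  The R wrappers in
// R/gassom.R own all bookkeeping (annealing schedules, validation);
// these routines only do the dense linear algebra of encoding and the
// basis update.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Encode a window batch: responses/errors per unit, plus the sticky
// Markov filtering posterior over units.
// [[Rcpp::export(name = ".gassom_encode_core")]]
List gassom_encode_core(const arma::mat& X, const arma::mat& Phi,
                        double sigma_n, double stay, bool smooth) {
  const arma::uword n = X.n_rows, J = Phi.n_cols / 2;
  arma::mat P = X * Phi;                       // n x 2J
  arma::mat resp(n, J), err(n, J);
  arma::vec x2 = arma::sum(arma::square(X), 1);
  for (arma::uword j = 0; j < J; ++j) {
    resp.col(j) = arma::square(P.col(2 * j)) + arma::square(P.col(2 * j + 1));
    err.col(j) = x2 - resp.col(j);
  }
  err.clamp(0.0, arma::datum::inf);
  // emissions, row-max normalized in log space
  arma::mat logem = -err / (2.0 * sigma_n * sigma_n);
  arma::vec rowmax = arma::max(logem, 1);
  logem.each_col() -= rowmax;
  arma::mat em = arma::exp(logem);
  arma::mat post(n, J);
  if (smooth && n > 1) {
    const double mix = (1.0 - stay) / J;
    arma::rowvec alpha = em.row(0) / arma::accu(em.row(0));
    post.row(0) = alpha;
    for (arma::uword i = 1; i < n; ++i) {
      alpha = em.row(i) % (stay * alpha + mix);
      alpha /= arma::accu(alpha);
      post.row(i) = alpha;
    }
  } else {
    post = em;
    post.each_col() /= arma::sum(em, 1);
  }
  return List::create(_["responses"] = resp, _["errors"] = err,
                      _["posterior"] = post, _["proj"] = P,
                      _["expected_error"] = arma::vec(arma::sum(post % err, 1)));
}

// Neighborhood-weighted batch step towards the response gradient,
// followed by per-unit Gram-Schmidt re-orthonormalization.
// [[Rcpp::export(name = ".gassom_update_core")]]
arma::mat gassom_update_core(const arma::mat& X, const arma::mat& P,
                             const arma::mat& post, const arma::mat& H,
                             const arma::mat& Phi, double eta) {
  const arma::uword J = Phi.n_cols / 2;
  arma::mat W = post * H;                      // n x J
  arma::rowvec Wsum = arma::sum(W, 0);
  arma::mat W2(W.n_rows, 2 * J);
  for (arma::uword j = 0; j < J; ++j) {
    W2.col(2 * j) = W.col(j);
    W2.col(2 * j + 1) = W.col(j);
  }
  arma::mat G = X.t() * (W2 % P);              // d x 2J
  arma::mat out = Phi;
  for (arma::uword j = 0; j < J; ++j) {
    double s = eta / std::max(Wsum(j), 1e-8);
    arma::vec u = Phi.col(2 * j) + s * G.col(2 * j);
    arma::vec v = Phi.col(2 * j + 1) + s * G.col(2 * j + 1);
    double nu = arma::norm(u);
    if (nu < 1e-12) nu = 1.0;
    u /= nu;
    v -= u * arma::dot(u, v);
    double nv = arma::norm(v);
    if (nv < 1e-9) continue;  // degenerate: leave the R wrapper to fix
    v /= nv;
    out.col(2 * j) = u;
    out.col(2 * j + 1) = v;
  }
  return out;
}
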