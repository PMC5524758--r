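// Gibbs sampler for the kernel variance-partition model, run in the
// eigenbasis of the kernel so each iteration is O(n). Uses R's RNG so
// draws are reproducible under set.seed().
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Model (rotated by the kernel eigenvectors E, so G = diag(lambda)):
//   ytilde = Wtilde beta + delta + e,  delta_k ~ N(0, sg2 * lambda_k),
//   e ~ N(0, se2 * I); scaled-inverse-chi^2 priors on sg2, se2.
// Returns kept draws of (sg2, se2, var_u) where var_u is the realized
// sample variance of u = E delta (norm-preserved by the rotation).
// [[Rcpp::export]]
arma::mat gibbs_kernel_cpp(const arma::vec& ytilde, const arma::mat& Wtilde,
                           const arma::vec& lambda, const arma::vec& esum,
                           double prior_df, double prior_scale_g,
                           double prior_scale_e,
                           int n_iter, int burn_in, int thin,
                           double init_sg2, double init_se2) {
  const int n = ytilde.n_elem;
  const int p = Wtilde.n_cols;
  const arma::mat WtW = Wtilde.t() * Wtilde;
  const arma::mat R = arma::chol(WtW);           // upper triangular
  const arma::mat Rinv = arma::inv(arma::trimatu(R));
  const arma::mat WtWinvWt = arma::solve(WtW, Wtilde.t());

  arma::uvec pos = arma::find(lambda > 1e-10 * arma::max(lambda));
  const int q = pos.n_elem;

  double sg2 = init_sg2, se2 = init_se2;
  arma::vec delta(n, arma::fill::zeros);
  arma::vec beta(p, arma::fill::zeros);

  const int n_keep = (n_iter - burn_in) / thin;
  arma::mat out(n_keep, 3);
  int kept = 0;

  for (int it = 1; it <= n_iter; ++it) {
    // beta | rest
    arma::vec mu_b = WtWinvWt * (ytilde - delta);
    arma::vec z(p);
    for (int j = 0; j < p; ++j) z(j) = R::norm_rand();
    beta = mu_b + std::sqrt(se2) * (Rinv * z);

    // delta | rest (independent normals in the eigenbasis)
    arma::vec r = ytilde - Wtilde * beta;
    delta.zeros();
    double quad = 0.0;                            // sum delta_k^2 / lambda_k
    for (int k = 0; k < q; ++k) {
      int idx = pos(k);
      double prec = 1.0 / se2 + 1.0 / (sg2 * lambda(idx));
      double v = 1.0 / prec;
      double m = v * r(idx) / se2;
      double d = m + std::sqrt(v) * R::norm_rand();
      delta(idx) = d;
      quad += d * d / lambda(idx);
    }

    // sg2 | delta  ~ scaled-inv-chi^2(prior_df + q, ...)
    sg2 = (quad + prior_df * prior_scale_g) / R::rchisq(prior_df + q);

    // se2 | rest
    double sse = arma::accu(arma::square(r - delta));
    se2 = (sse + prior_df * prior_scale_e) / R::rchisq(prior_df + n);

    if (it > burn_in && (it - burn_in) % thin == 0 && kept < n_keep) {
      double usum = arma::dot(esum, delta);
      double var_u = (arma::dot(delta, delta) - usum * usum / n) / (n - 1.0);
      out(kept, 0) = sg2;
      out(kept, 1) = se2;
      out(kept, 2) = var_u;
      ++kept;
    }
  }
  return out.rows(0, kept - 1);
}
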