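// Bayes B spike-and-slab Gibbs sampler for whole-genome regression.
//
// Model: y = 1*mu + sum_j delta_j * x_j * beta_j + e
//   delta_j ~ Bernoulli(probIn), beta_j | s2_j ~ N(0, s2_j),
//   s2_j ~ scaled-inv-chi2(df_beta, S0_beta), sigma2_e ~ scaled-inv-chi2,
//   probIn ~ Beta (pseudo-count parameterisation), optionally fixed.
// The scaled-t slab arises by integrating beta_j over s2_j.
// Uses R's RNG so results are reproducible under set.seed() from R.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// [[Rcpp::export(name = ".bayesb_mcmc")]]
List bayesb_mcmc(const arma::vec& y, const arma::mat& W,
                 int n_iter, int burn_in, int thin,
                 double df_beta, double S0_beta,
                 double df_e, double S0_e,
                 double prob_in, double pi_counts, bool update_pi) {
  const int n = W.n_rows, m = W.n_cols;
  arma::vec xx(m);
  for (int j = 0; j < m; ++j) xx[j] = arma::dot(W.col(j), W.col(j));

  double mu = arma::mean(y);
  arma::vec beta(m, arma::fill::zeros);
  arma::ivec delta(m, arma::fill::zeros);
  arma::vec s2(m);
  double prior_mode = S0_beta / (df_beta + 2.0);
  s2.fill(prior_mode > 0 ? prior_mode : 1e-4);
  double sigma2_e = arma::var(y) * 0.5;
  if (sigma2_e <= 0) sigma2_e = 1e-8;
  double probIn = prob_in;

  arma::vec e = y - mu;

  int n_keep = (n_iter - burn_in) / thin;
  arma::vec post_mu(1, arma::fill::zeros);
  arma::vec post_beta(m, arma::fill::zeros);
  arma::vec post_incl(m, arma::fill::zeros);
  arma::vec chain_ve(n_keep, arma::fill::zeros);
  arma::vec chain_pi(n_keep, arma::fill::zeros);
  int kept = 0;

  for (int it = 0; it < n_iter; ++it) {
    // intercept
    double mu_new = mu + arma::mean(e) + R::rnorm(0.0, std::sqrt(sigma2_e / n));
    e -= (mu_new - mu);
    mu = mu_new;

    int n_in = 0;
    for (int j = 0; j < m; ++j) {
      if (xx[j] <= 0) { delta[j] = 0; beta[j] = 0.0; continue; }
      double b_old = delta[j] ? beta[j] : 0.0;
      // rhs = x_j' (e + x_j b_old): add the marker's own contribution back
      double rhs = arma::dot(W.col(j), e) + xx[j] * b_old;
      double C = xx[j] + sigma2_e / s2[j];
      double logodds = std::log(probIn / (1.0 - probIn)) +
        0.5 * rhs * rhs / (C * sigma2_e) +
        0.5 * std::log(sigma2_e / (s2[j] * C));
      double p1 = 1.0 / (1.0 + std::exp(-logodds));
      if (R::unif_rand() < p1) {
        double b_new = rhs / C + R::rnorm(0.0, std::sqrt(sigma2_e / C));
        e += W.col(j) * (b_old - b_new);
        beta[j] = b_new;
        delta[j] = 1;
        ++n_in;
      } else {
        if (delta[j]) e += W.col(j) * b_old;
        beta[j] = 0.0;
        delta[j] = 0;
      }
      // marker variance: conditional draw if in the model, prior draw if not
      double ssq = S0_beta + (delta[j] ? beta[j] * beta[j] : 0.0);
      s2[j] = ssq / R::rchisq(df_beta + (delta[j] ? 1.0 : 0.0));
    }

    if (update_pi) {
      double a = prob_in * pi_counts, b = (1.0 - prob_in) * pi_counts;
      probIn = R::rbeta(a + n_in, b + (m - n_in));
      probIn = std::min(std::max(probIn, 1e-6), 1.0 - 1e-6);
    }

    sigma2_e = (arma::dot(e, e) + S0_e) / R::rchisq(df_e + n);

    if (it >= burn_in && ((it - burn_in) % thin == 0) && kept < n_keep) {
      post_mu[0] += mu;
      post_beta += arma::conv_to<arma::vec>::from(delta) % beta;
      for (int j = 0; j < m; ++j) post_incl[j] += delta[j];
      chain_ve[kept] = sigma2_e;
      chain_pi[kept] = 1.0 - probIn;  // report pi as P(zero effect)
      ++kept;
    }
  }
  post_mu /= kept;
  post_beta /= kept;
  post_incl /= kept;

  return List::create(_["mu"] = post_mu[0],
                      _["beta"] = post_beta,
                      _["inclusion"] = post_incl,
                      _["sigma2_e_chain"] = chain_ve,
                      _["pi_chain"] = chain_pi,
                      _["n_samples"] = kept);
}
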