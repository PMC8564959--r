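// BayesCpi Gibbs sampler: mixture prior on SNP effects with a common
// effect variance, inclusion probability pi with a Beta prior.
// Uses R's RNG throughout so results are reproducible via set.seed().
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// scaled inverse chi-square draw: (df * scale) / chisq(df)
static inline double rinvchisq(double df, double scale) {
  return df * scale / R::rchisq(df);
}

// [[Rcpp::export(name = ".bayescpi_mcmc")]]
List bayescpi_mcmc(const arma::mat& Z,      // centred dosages, n x m
                   const arma::vec& y,
                   int n_cycles, int burn_in, int thin,
                   double alpha, double beta,
                   double nu_a, double s2_a_prior,
                   double nu_e, double s2_e_prior,
                   bool fix_pi, double pi_init) {
  const int n = Z.n_rows, m = Z.n_cols;
  arma::vec zz(m);
  for (int j = 0; j < m; ++j) zz(j) = arma::dot(Z.col(j), Z.col(j));

  double mu = arma::mean(y);
  arma::vec a(m, arma::fill::zeros);
  arma::ivec delta(m, arma::fill::zeros);
  double s2a = s2_a_prior;
  double s2e = s2_e_prior * nu_e / std::max(nu_e - 2.0, 1.0);
  double pi = pi_init;
  arma::vec ycorr = y - mu;

  const int n_saved_max = (n_cycles - burn_in) / thin;
  arma::vec sum_delta(m, arma::fill::zeros);
  arma::vec sum_da(m, arma::fill::zeros);
  arma::vec sum_da2(m, arma::fill::zeros);
  NumericVector samp_s2a(n_saved_max), samp_s2e(n_saved_max),
      samp_pi(n_saved_max);
  IntegerVector samp_size(n_saved_max);
  double sum_mu = 0.0;
  int n_saved = 0;

  for (int cyc = 1; cyc <= n_cycles; ++cyc) {
    // overall mean
    ycorr += mu;
    double mu_hat = arma::mean(ycorr);
    mu = R::rnorm(mu_hat, std::sqrt(s2e / n));
    ycorr -= mu;

    // SNP inclusion indicators and effects
    int m_in = 0;
    double ssa = 0.0;
    const double log_odds_prior = std::log(pi / (1.0 - pi));
    for (int j = 0; j < m; ++j) {
      if (delta(j) == 1) ycorr += Z.col(j) * a(j);
      const double rhs = arma::dot(Z.col(j), ycorr);
      const double v0 = zz(j) * s2e;
      const double v1 = zz(j) * zz(j) * s2a + v0;
      const double log_lr = 0.5 * (std::log(v0 / v1) +
                                   rhs * rhs * (1.0 / v0 - 1.0 / v1));
      const double lo = log_odds_prior + log_lr;
      const double p1 = 1.0 / (1.0 + std::exp(-lo));
      if (R::unif_rand() < p1) {
        const double C = zz(j) + s2e / s2a;
        const double ahat = rhs / C;
        a(j) = R::rnorm(ahat, std::sqrt(s2e / C));
        delta(j) = 1;
        ycorr -= Z.col(j) * a(j);
        ++m_in;
        ssa += a(j) * a(j);
      } else {
        a(j) = 0.0;
        delta(j) = 0;
      }
    }

    // common effect variance, residual variance, inclusion probability
    s2a = rinvchisq(nu_a + m_in, (ssa + nu_a * s2_a_prior) / (nu_a + m_in));
    const double sse = arma::dot(ycorr, ycorr);
    s2e = rinvchisq(nu_e + n, (sse + nu_e * s2_e_prior) / (nu_e + n));
    if (!fix_pi) pi = R::rbeta(alpha + m_in, beta + (m - m_in));

    if (cyc > burn_in && (cyc - burn_in) % thin == 0) {
      for (int j = 0; j < m; ++j) {
        if (delta(j) == 1) {
          sum_delta(j) += 1.0;
          const double da = a(j);
          sum_da(j) += da;
          sum_da2(j) += da * da;
        }
      }
      samp_s2a[n_saved] = s2a;
      samp_s2e[n_saved] = s2e;
      samp_pi[n_saved] = pi;
      samp_size[n_saved] = m_in;
      sum_mu += mu;
      ++n_saved;
    }
  }

  return List::create(
      _["pip"] = NumericVector(sum_delta.begin(), sum_delta.end()) /
                 (double)n_saved,
      _["mean_effect"] = NumericVector(sum_da.begin(), sum_da.end()) /
                         (double)n_saved,
      _["mean_effect2"] = NumericVector(sum_da2.begin(), sum_da2.end()) /
                          (double)n_saved,
      _["mu"] = sum_mu / n_saved,
      _["s2a"] = samp_s2a, _["s2e"] = samp_s2e, _["pi"] = samp_pi,
      _["model_size"] = samp_size, _["n_saved"] = n_saved);
}
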