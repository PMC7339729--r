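#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Inverse-gamma draw parameterized by shape and rate:
// X ~ IG(shape, rate)  <=>  1/X ~ Gamma(shape, rate)
static double rinvgamma(double shape, double rate) {
  return 1.0 / R::rgamma(shape, 1.0 / rate);
}

// Categorical draw from unnormalized log-probabilities, using R's RNG.
static int sample_discrete(const arma::vec &logp) {
  arma::vec p = arma::exp(logp - logp.max());
  p /= arma::accu(p);
  double u = R::runif(0.0, 1.0), c = 0.0;
  for (arma::uword j = 0; j < p.n_elem; ++j) {
    c += p(j);
    if (u <= c) return (int)j;
  }
  return (int)p.n_elem - 1;
}

// Draw from N(mean, P^{-1}) given precision P via Cholesky.
static arma::vec mvn_prec(const arma::mat &P, const arma::vec &rhs) {
  arma::mat U = arma::chol(P);                    // P = U' U, U upper
  arma::vec mean = arma::solve(arma::trimatu(U),
                   arma::solve(arma::trimatl(U.t()), rhs));
  arma::vec z(P.n_rows);
  for (arma::uword i = 0; i < z.n_elem; ++i) z(i) = R::rnorm(0.0, 1.0);
  return mean + arma::solve(arma::trimatu(U), z);
}

// Per-day Gibbs sampler for the downscaler regression
//   y_i = beta0 + w_i + beta1 * x~_i + eps_i,  eps ~ N(0, sigma2),
//   w ~ GP(0, tau2 * exp(-d/rho)) at the day's site locations.
// X holds the kernel-weighted regressor for each candidate kernel decay
// (one column per candidate); Qs holds the inverse site correlation matrix
// for each candidate rho. rho and the kernel decay are updated by discrete
// conditional draws over their candidate grids. Setting fixed_* > 0 pins a
// parameter (used by the oracle cross-checks).
// [[Rcpp::export]]
List ds_gibbs_cpp(const arma::vec &y,
                  const arma::mat &X,
                  const List &Qs,
                  const arma::vec &logdetQ,
                  const arma::vec &prior_beta_mean,
                  const arma::vec &prior_beta_var,
                  double a_sigma, double b_sigma,
                  double a_tau, double b_tau,
                  int n_iter, int n_burn, int thin,
                  double fixed_sigma2, double fixed_tau2,
                  int fixed_rho, int fixed_decay,
                  double init_sigma2, double init_tau2)
{
  const int n = (int)y.n_elem, K = (int)X.n_cols, J = Qs.size();
  std::vector<arma::mat> Q((size_t)J);
  for (int j = 0; j < J; ++j) Q[(size_t)j] = as<arma::mat>(Qs[j]);

  int rho_idx = fixed_rho > 0 ? fixed_rho - 1 : J / 2;
  int dec_idx = fixed_decay > 0 ? fixed_decay - 1 : K / 2;
  double sigma2 = fixed_sigma2 > 0 ? fixed_sigma2 : init_sigma2;
  double tau2   = fixed_tau2   > 0 ? fixed_tau2   : init_tau2;
  arma::vec w(n, arma::fill::zeros);
  arma::vec gam(2, arma::fill::zeros);
  arma::vec ones(n, arma::fill::ones);

  const int n_keep = (n_iter - n_burn) / thin;
  arma::mat beta_out(n_keep, 2), w_out(n_keep, n);
  arma::vec s2_out(n_keep), t2_out(n_keep);
  arma::ivec rho_out(n_keep), dec_out(n_keep);

  int keep = 0;
  for (int it = 1; it <= n_iter; ++it) {
    arma::mat Z = arma::join_rows(ones, X.col(dec_idx));

    // (beta0, beta1 | .) conjugate bivariate normal
    {
      arma::mat A = Z.t() * Z / sigma2;
      A(0, 0) += 1.0 / prior_beta_var(0);
      A(1, 1) += 1.0 / prior_beta_var(1);
      arma::vec rhs = Z.t() * (y - w) / sigma2 + prior_beta_mean / prior_beta_var;
      gam = mvn_prec(A, rhs);
    }

    // (w | .) conjugate multivariate normal with GP prior precision Q/tau2
    {
      arma::mat P = Q[(size_t)rho_idx] / tau2;
      P.diag() += 1.0 / sigma2;
      arma::vec rhs = (y - Z * gam) / sigma2;
      w = mvn_prec(P, rhs);
    }

    // (sigma2 | .) inverse-gamma
    if (fixed_sigma2 <= 0) {
      arma::vec resid = y - Z * gam - w;
      sigma2 = rinvgamma(a_sigma + 0.5 * n,
                         b_sigma + 0.5 * arma::dot(resid, resid));
    }

    // quadratic forms w' Q_j w reused by tau2 and rho updates
    arma::vec qf(J);
    for (int j = 0; j < J; ++j)
      qf(j) = arma::as_scalar(w.t() * Q[(size_t)j] * w);

    // (tau2 | .) inverse-gamma
    if (fixed_tau2 <= 0)
      tau2 = rinvgamma(a_tau + 0.5 * n, b_tau + 0.5 * qf(rho_idx));

    // (rho | .) discrete over candidates, uniform prior mass
    if (fixed_rho <= 0 && J > 1) {
      arma::vec lp(J);
      for (int j = 0; j < J; ++j)
        lp(j) = 0.5 * logdetQ(j) - 0.5 * qf(j) / tau2;
      rho_idx = sample_discrete(lp);
    }

    // (kernel decay | .) discrete over candidate regressors
    if (fixed_decay <= 0 && K > 1) {
      arma::vec lp(K);
      for (int k = 0; k < K; ++k) {
        arma::vec r = y - gam(0) - gam(1) * X.col(k) - w;
        lp(k) = -0.5 * arma::dot(r, r) / sigma2;
      }
      dec_idx = sample_discrete(lp);
    }

    if (it > n_burn && (it - n_burn) % thin == 0 && keep < n_keep) {
      beta_out.row(keep) = gam.t();
      w_out.row(keep) = w.t();
      s2_out(keep) = sigma2;
      t2_out(keep) = tau2;
      rho_out(keep) = rho_idx + 1;
      dec_out(keep) = dec_idx + 1;
      ++keep;
    }
  }

  return List::create(
    _["beta"] = beta_out, _["w"] = w_out,
    _["sigma2"] = s2_out, _["tau2"] = t2_out,
    _["rho_idx"] = rho_out, _["decay_idx"] = dec_out);
}
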