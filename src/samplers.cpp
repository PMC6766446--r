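// Gibbs samplers for the network's node regressions.
//
// Linear nodes:   y = X b + e,  e ~ N(0, s2),  b_j ~ N(0, prior_sd^2),
//                 s ~ half-Cauchy(hc_scale) via the inverse-gamma mixture
//                 s2 | a ~ IG(1/2, 1/a), a ~ IG(1/2, 1/hc_scale^2).
// Logistic nodes: logit P(y=1) = X b, b_j ~ N(0, prior_sd^2), sampled by
//                 Polya-Gamma augmentation (Polson, Scott & Windle 2013;
//                 Devroye-type exact sampler for PG(1, z)).
//
// All randomness goes through R's RNG, so set.seed() on the R side makes
// every draw reproducible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double TRUNC = 0.64; // truncation point of the two-piece proposal

// coefficients of the alternating series for the Jacobi density
static double a_coef(int n, double x) {
  double k = n + 0.5;
  if (x <= TRUNC) {
    return M_PI * k * std::pow(2.0 / (M_PI * x), 1.5) *
           std::exp(-2.0 * k * k / x);
  }
  return M_PI * k * std::exp(-0.5 * k * k * M_PI * M_PI * x);
}

// CDF at x of inverse-Gaussian(mu = 1/z, lambda = 1); z = 0 gives the
// one-sided stable (Levy) limit.
static double pigauss(double x, double z) {
  double rx = 1.0 / std::sqrt(x);
  double b = rx * (x * z - 1.0);
  double a = rx * (x * z + 1.0);
  return R::pnorm(b, 0.0, 1.0, 1, 0) +
         std::exp(2.0 * z) * R::pnorm(-a, 0.0, 1.0, 1, 0);
}

// inverse-Gaussian(mu = 1/z, 1) truncated to (0, t)
static double rtigauss(double z, double t) {
  double x = t + 1.0;
  double mu = (z > 1e-12) ? 1.0 / z : R_PosInf;
  if (mu > t) {
    // rejection against the truncated Levy density
    double alpha = 0.0;
    while (unif_rand() > alpha) {
      double e1, e2;
      do {
        e1 = exp_rand();
        e2 = exp_rand();
      } while (e1 * e1 > 2.0 * e2 / t);
      x = t / ((1.0 + t * e1) * (1.0 + t * e1));
      alpha = std::exp(-0.5 * z * z * x);
    }
  } else {
    while (x > t) {
      double y = norm_rand();
      y = y * y;
      double muy = mu * y;
      x = mu + 0.5 * mu * muy -
          0.5 * mu * std::sqrt(4.0 * muy + muy * muy);
      if (unif_rand() > mu / (mu + x)) x = mu * mu / x;
    }
  }
  return x;
}

// one exact draw from PG(1, z)
static double rpg1(double z) {
  z = std::fabs(z) * 0.5;
  double K = 0.125 * M_PI * M_PI + 0.5 * z * z;
  double p = (M_PI / (2.0 * K)) * std::exp(-K * TRUNC);
  double q = 2.0 * std::exp(-z) * pigauss(TRUNC, z);
  for (;;) {
    double x;
    if (unif_rand() < p / (p + q)) {
      x = TRUNC + exp_rand() / K; // exponential tail
    } else {
      x = rtigauss(z, TRUNC);
    }
    // alternating-series accept/reject
    double s = a_coef(0, x);
    double y = unif_rand() * s;
    int n = 0;
    for (;;) {
      ++n;
      if (n % 2 == 1) {
        s -= a_coef(n, x);
        if (y <= s) return 0.25 * x;
      } else {
        s += a_coef(n, x);
        if (y > s) break; // reject, draw a new x
      }
    }
  }
}

//' @title Polya-Gamma PG(1, z) variates
//' @description Draws from the Polya-Gamma distribution PG(1, z), used to
//'   augment logistic likelihoods. Exposed mainly for testing the sampler
//'   against the closed-form moments.
//' @param n number of draws
//' @param z vector of tilting parameters (recycled)
//' @return numeric vector of draws
//' @keywords internal
// [[Rcpp::export]]
NumericVector rpg(int n, NumericVector z) {
  NumericVector out(n);
  int m = z.size();
  for (int i = 0; i < n; ++i) out[i] = rpg1(z[i % m]);
  return out;
}

static double rinvgamma(double shape, double rate) {
  return 1.0 / R::rgamma(shape, 1.0 / rate);
}

// draw b ~ N(P^{-1} r, P^{-1}) given precision P and linear term r
static arma::vec draw_mvn(const arma::mat& P, const arma::vec& r) {
  arma::mat L = arma::chol(P, "lower");
  arma::vec mu = arma::solve(arma::trimatu(L.t()),
                             arma::solve(arma::trimatl(L), r));
  arma::vec zdraw(r.n_elem);
  for (arma::uword j = 0; j < r.n_elem; ++j) zdraw[j] = norm_rand();
  return mu + arma::solve(arma::trimatu(L.t()), zdraw);
}

// [[Rcpp::export]]
List cpp_gibbs_linear(const arma::vec& y, const arma::mat& X,
                      int n_iter, int n_burnin, int thin,
                      double prior_sd, double hc_scale,
                      const arma::vec& beta_init, double sigma_init) {
  int n = y.n_elem, p = X.n_cols;
  arma::mat XtX = X.t() * X;
  arma::vec Xty = X.t() * y;
  double prior_prec = 1.0 / (prior_sd * prior_sd);
  double hc2 = hc_scale * hc_scale;

  arma::vec beta = beta_init;
  double sigma2 = sigma_init * sigma_init;
  double aux = 1.0;

  int n_keep = (n_iter - n_burnin) / thin;
  arma::mat beta_out(n_keep, p);
  arma::vec sigma_out(n_keep);

  int k = 0;
  for (int it = 0; it < n_iter; ++it) {
    // beta | sigma2
    arma::mat P = XtX / sigma2;
    P.diag() += prior_prec;
    beta = draw_mvn(P, Xty / sigma2);
    // sigma2 | beta, aux  and  aux | sigma2  (half-Cauchy mixture)
    arma::vec resid = y - X * beta;
    double ssr = arma::dot(resid, resid);
    sigma2 = rinvgamma(0.5 * (n + 1.0), 1.0 / aux + 0.5 * ssr);
    aux = rinvgamma(1.0, 1.0 / hc2 + 1.0 / sigma2);
    if (it >= n_burnin && (it - n_burnin) % thin == 0) {
      beta_out.row(k) = beta.t();
      sigma_out[k] = std::sqrt(sigma2);
      ++k;
    }
  }
  return List::create(_["beta"] = beta_out, _["sigma"] = sigma_out);
}

// [[Rcpp::export]]
List cpp_gibbs_logistic(const arma::vec& y, const arma::mat& X,
                        int n_iter, int n_burnin, int thin,
                        double prior_sd, const arma::vec& beta_init) {
  int n = y.n_elem, p = X.n_cols;
  double prior_prec = 1.0 / (prior_sd * prior_sd);
  arma::vec kappa = y - 0.5;
  arma::vec Xtk = X.t() * kappa;

  arma::vec beta = beta_init;
  arma::vec omega(n);

  int n_keep = (n_iter - n_burnin) / thin;
  arma::mat beta_out(n_keep, p);

  int k = 0;
  for (int it = 0; it < n_iter; ++it) {
    arma::vec eta = X * beta;
    for (int i = 0; i < n; ++i) omega[i] = rpg1(eta[i]);
    arma::mat P = X.t() * (X.each_col() % omega);
    P.diag() += prior_prec;
    beta = draw_mvn(P, Xtk);
    if (it >= n_burnin && (it - n_burnin) % thin == 0) {
      beta_out.row(k) = beta.t();
      ++k;
    }
  }
  return List::create(_["beta"] = beta_out);
}
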