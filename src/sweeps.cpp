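#include <Rcpp.h>
using namespace Rcpp;

// One full Gibbs sweep of the BayesC-pi sampler. Update order:
// mu -> (delta_j, alpha_j) for j = 1..p (ascending; effects are not
// conditionally independent given the variances, so the marker loop is
// deliberately sequential) -> sigma2_alpha -> sigma2_e -> pi.
// The residual vector e = y - 1*mu - Z*alpha is maintained incrementally.
// All randomness comes from R's RNG so that draws are reproducible under
// the package's stream discipline.

static inline double clamp_pi(double p) {
  const double eps = 1e-12;
  if (p < eps) return eps;
  if (p > 1.0 - eps) return 1.0 - eps;
  return p;
}

// [[Rcpp::export(name = ".bayesc_sweep")]]
List bayesc_sweep(const NumericMatrix& Z, NumericVector e_, double mu,
                  NumericVector alpha_, IntegerVector delta_, double pi,
                  double s2a, double s2e, const NumericVector& csum,
                  double nu_a, double S2a, double nu_e, double S2e,
                  bool update_pi, bool fix_mu, bool fix_s2a, bool fix_s2e) {
  const int n = Z.nrow(), p = Z.ncol();
  NumericVector e = clone(e_);
  NumericVector alpha = clone(alpha_);
  IntegerVector delta = clone(delta_);

  // intercept (flat prior): mu | . ~ N(mean(y - Z alpha), s2e / n)
  if (!fix_mu && n > 0) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += e[i] + mu;
    double mu_new = R::rnorm(s / n, std::sqrt(s2e / n));
    double d = mu_new - mu;
    for (int i = 0; i < n; ++i) e[i] -= d;
    mu = mu_new;
  }

  const double pic = clamp_pi(pi);
  const double lo_prior = std::log((1.0 - pic) / pic);

  for (int j = 0; j < p; ++j) {
    const double c = csum[j];
    double aj = alpha[j];
    if (delta[j] == 1 && aj != 0.0)
      for (int i = 0; i < n; ++i) e[i] += Z(i, j) * aj;
    double rhs = 0.0;
    for (int i = 0; i < n; ++i) rhs += Z(i, j) * e[i];

    double p_incl;
    if (pi <= 0.0) {
      p_incl = 1.0; // every marker in the model (BayesC pi = 0)
    } else if (pi >= 1.0) {
      p_incl = 0.0; // all effects null with certainty
    } else if (c > 0.0) {
      const double v0 = c * s2e;              // var(rhs) given delta = 0
      const double v1 = c * c * s2a + c * s2e; // var(rhs) given delta = 1
      const double logodds = lo_prior + 0.5 * std::log(v0 / v1) +
                             0.5 * rhs * rhs * (1.0 / v0 - 1.0 / v1);
      p_incl = 1.0 / (1.0 + std::exp(-logodds));
    } else {
      // no data on this marker: prior odds
      p_incl = 1.0 / (1.0 + std::exp(-lo_prior));
    }

    if (unif_rand() < p_incl) {
      const double C = c + s2e / s2a;
      const double a_new = R::rnorm(rhs / C, std::sqrt(s2e / C));
      alpha[j] = a_new;
      delta[j] = 1;
      for (int i = 0; i < n; ++i) e[i] -= Z(i, j) * a_new;
    } else {
      alpha[j] = 0.0;
      delta[j] = 0;
    }
  }

  int k = 0;
  double ssa = 0.0;
  for (int j = 0; j < p; ++j)
    if (delta[j] == 1) { ++k; ssa += alpha[j] * alpha[j]; }

  if (!fix_s2a) {
    if (k > 0)
      s2a = (ssa + nu_a * S2a) / R::rchisq(nu_a + k);
    else
      s2a = (nu_a * S2a) / R::rchisq(nu_a); // no marker in: prior draw
  }

  if (!fix_s2e) {
    double sse = 0.0;
    for (int i = 0; i < n; ++i) sse += e[i] * e[i];
    s2e = (sse + nu_e * S2e) / R::rchisq(nu_e + n);
  }

  if (update_pi)
    pi = R::rbeta((double)(p - k) + 1.0, (double)k + 1.0);

  return List::create(_["mu"] = mu, _["alpha"] = alpha, _["delta"] = delta,
                      _["pi"] = pi, _["s2a"] = s2a, _["s2e"] = s2e,
                      _["e"] = e);
}

// Inverse-Gaussian draw (Michael, Schucany & Haas transform), using R's RNG.
static double rinvgauss1(double mu, double lambda) {
  double z = norm_rand();
  double v = z * z;
  double x = mu + mu * mu * v / (2.0 * lambda) -
             mu / (2.0 * lambda) *
                 std::sqrt(4.0 * mu * lambda * v + mu * mu * v * v);
  if (x <= 0.0) x = 1e-300; // numeric underflow guard
  if (unif_rand() <= mu / (mu + x)) return x;
  return mu * mu / x;
}

// [[Rcpp::export(name = ".rinvgauss_cpp")]]
NumericVector rinvgauss_cpp(int n, double mu, double lambda) {
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rinvgauss1(mu, lambda);
  return out;
}

// One full Gibbs sweep of the Bayesian LASSO under the exponential-mixture
// hierarchy: beta_j | tau2_j, s2e ~ N(0, tau2_j * s2e); tau2_j ~
// Exp(lambda2 / 2); lambda2 ~ Gamma(shape, rate). Update order:
// mu -> beta_1..beta_p -> tau2_1..tau2_p -> lambda2 -> sigma2_e.
// [[Rcpp::export(name = ".blasso_sweep")]]
List blasso_sweep(const NumericMatrix& X, NumericVector e_, double mu,
                  NumericVector beta_, NumericVector tau2_, double lambda2,
                  double s2e, const NumericVector& csum, double shape,
                  double rate, double nu_e, double S2e, bool fix_mu,
                  bool fix_tau2, bool fix_lambda2, bool fix_s2e) {
  const int n = X.nrow(), p = X.ncol();
  NumericVector e = clone(e_);
  NumericVector beta = clone(beta_);
  NumericVector tau2 = clone(tau2_);

  if (!fix_mu && n > 0) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += e[i] + mu;
    double mu_new = R::rnorm(s / n, std::sqrt(s2e / n));
    double d = mu_new - mu;
    for (int i = 0; i < n; ++i) e[i] -= d;
    mu = mu_new;
  }

  for (int j = 0; j < p; ++j) {
    double bj = beta[j];
    if (bj != 0.0)
      for (int i = 0; i < n; ++i) e[i] += X(i, j) * bj;
    double rhs = 0.0;
    for (int i = 0; i < n; ++i) rhs += X(i, j) * e[i];
    const double C = csum[j] + 1.0 / tau2[j];
    const double b_new = R::rnorm(rhs / C, std::sqrt(s2e / C));
    beta[j] = b_new;
    for (int i = 0; i < n; ++i) e[i] -= X(i, j) * b_new;
  }

  if (!fix_tau2) {
    for (int j = 0; j < p; ++j) {
      const double b2 = beta[j] * beta[j];
      if (b2 < 1e-280) {
        tau2[j] = R::rexp(2.0 / lambda2); // conditional reduces to the prior
      } else {
        const double mu_ig = std::sqrt(lambda2 * s2e / b2);
        tau2[j] = 1.0 / rinvgauss1(mu_ig, lambda2);
      }
    }
  }

  double sum_tau2 = 0.0;
  for (int j = 0; j < p; ++j) sum_tau2 += tau2[j];

  if (!fix_lambda2)
    lambda2 = R::rgamma(shape + p, 1.0 / (rate + sum_tau2 / 2.0));

  if (!fix_s2e) {
    double sse = 0.0, ssb = 0.0;
    for (int i = 0; i < n; ++i) sse += e[i] * e[i];
    for (int j = 0; j < p; ++j) ssb += beta[j] * beta[j] / tau2[j];
    s2e = (sse + ssb + nu_e * S2e) / R::rchisq(nu_e + n + p);
  }

  return List::create(_["mu"] = mu, _["beta"] = beta, _["tau2"] = tau2,
                      _["lambda2"] = lambda2, _["s2e"] = s2e, _["e"] = e);
}
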