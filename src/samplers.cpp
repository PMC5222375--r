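// Gibbs samplers for the Bayesian whole-genome regressions.
// Genotype matrices arrive column-centred from R; all randomness comes
// from R's RNG so set.seed() upstream makes chains reproducible.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// inverse-Gaussian draw (Michael, Schucany & Haas)
static double rinvgauss1(double mu, double lambda) {
  double nu = norm_rand();
  double y = nu * nu;
  double x = mu + mu * mu * y / (2.0 * lambda) -
             mu / (2.0 * lambda) *
                 std::sqrt(4.0 * mu * lambda * y + mu * mu * y * y);
  if (x <= 0.0) x = 1e-12;
  if (unif_rand() <= mu / (mu + x)) return x;
  return mu * mu / x;
}

static void check_state(double s2e, int it) {
  if (!std::isfinite(s2e) || s2e <= 0.0) {
    stop("divergent chain (non-finite state) at iteration %d", it);
  }
}

// Bayes A: beta_j ~ N(0, s2_j), s2_j ~ scaled-inv-chisq(df0, S0)
// [[Rcpp::export]]
List bayes_a_cpp(NumericMatrix X, NumericVector y, int niter, int burn,
                 int thin, double df0, double S0, double dfe, double Se) {
  int n = X.nrow(), p = X.ncol();
  std::vector<double> xtx(p), beta(p, 0.0), s2(p, std::max(S0, 1e-8));
  for (int j = 0; j < p; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += X(i, j) * X(i, j);
    xtx[j] = s;
  }
  double mu = mean(y);
  std::vector<double> e(n);
  for (int i = 0; i < n; ++i) e[i] = y[i] - mu;
  double s2e = var(y) / 2.0 + 1e-8;

  NumericVector beta_sum(p);
  double mu_sum = 0.0, s2e_sum = 0.0;
  int nsamp = 0;

  for (int it = 1; it <= niter; ++it) {
    // intercept
    double ebar = 0.0;
    for (int i = 0; i < n; ++i) ebar += e[i];
    ebar /= n;
    double mu_new = ::Rf_rnorm(mu + ebar, std::sqrt(s2e / n));
    for (int i = 0; i < n; ++i) e[i] += mu - mu_new;
    mu = mu_new;
    // marker effects
    for (int j = 0; j < p; ++j) {
      if (xtx[j] <= 0.0) continue;
      double rhs = xtx[j] * beta[j];
      for (int i = 0; i < n; ++i) rhs += X(i, j) * e[i];
      double cj = xtx[j] + s2e / s2[j];
      double bj = ::Rf_rnorm(rhs / cj, std::sqrt(s2e / cj));
      double d = beta[j] - bj;
      if (d != 0.0) for (int i = 0; i < n; ++i) e[i] += X(i, j) * d;
      beta[j] = bj;
      s2[j] = (bj * bj + df0 * S0) / ::Rf_rchisq(df0 + 1.0);
    }
    // residual variance
    double sse = 0.0;
    for (int i = 0; i < n; ++i) sse += e[i] * e[i];
    s2e = (sse + dfe * Se) / ::Rf_rchisq((double)n + dfe);
    check_state(s2e, it);

    if (it > burn && (it - burn) % thin == 0) {
      ++nsamp;
      mu_sum += mu;
      s2e_sum += s2e;
      for (int j = 0; j < p; ++j) beta_sum[j] += beta[j];
    }
    if (it % 256 == 0) Rcpp::checkUserInterrupt();
  }
  for (int j = 0; j < p; ++j) beta_sum[j] /= nsamp;
  return List::create(_["mu"] = mu_sum / nsamp, _["effects"] = beta_sum,
                      _["sigma2e"] = s2e_sum / nsamp,
                      _["n_samples"] = nsamp);
}

// Bayes B: point mass at zero with prior exclusion probability pi_zero
// [[Rcpp::export]]
List bayes_b_cpp(NumericMatrix X, NumericVector y, int niter, int burn,
                 int thin, double df0, double S0, double dfe, double Se,
                 double pi_zero) {
  int n = X.nrow(), p = X.ncol();
  std::vector<double> xtx(p), beta(p, 0.0), s2(p, std::max(S0, 1e-8));
  std::vector<int> delta(p, 1);
  for (int j = 0; j < p; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += X(i, j) * X(i, j);
    xtx[j] = s;
  }
  double mu = mean(y);
  std::vector<double> e(n);
  for (int i = 0; i < n; ++i) e[i] = y[i] - mu;
  double s2e = var(y) / 2.0 + 1e-8;
  double log_prior_odds = std::log((1.0 - pi_zero) / pi_zero);

  NumericVector beta_sum(p), incl_sum(p);
  double mu_sum = 0.0, s2e_sum = 0.0;
  int nsamp = 0;

  for (int it = 1; it <= niter; ++it) {
    double ebar = 0.0;
    for (int i = 0; i < n; ++i) ebar += e[i];
    ebar /= n;
    double mu_new = ::Rf_rnorm(mu + ebar, std::sqrt(s2e / n));
    for (int i = 0; i < n; ++i) e[i] += mu - mu_new;
    mu = mu_new;

    for (int j = 0; j < p; ++j) {
      if (xtx[j] <= 0.0) continue;
      double r = xtx[j] * beta[j];
      for (int i = 0; i < n; ++i) r += X(i, j) * e[i];
      // marginal likelihood of r with beta_j integrated out
      double v1 = xtx[j] * xtx[j] * s2[j] + xtx[j] * s2e;
      double v0 = xtx[j] * s2e;
      double lodds = (pi_zero <= 0.0) ? INFINITY
        : log_prior_odds - 0.5 * (std::log(v1) - std::log(v0)) -
          0.5 * r * r * (1.0 / v1 - 1.0 / v0);
      double p1 = 1.0 / (1.0 + std::exp(-lodds));
      int dj = (unif_rand() < p1) ? 1 : 0;
      double bj = 0.0;
      if (dj == 1) {
        double cj = xtx[j] + s2e / s2[j];
        bj = ::Rf_rnorm(r / cj, std::sqrt(s2e / cj));
      }
      double d = beta[j] - bj;
      if (d != 0.0) for (int i = 0; i < n; ++i) e[i] += X(i, j) * d;
      beta[j] = bj;
      delta[j] = dj;
      s2[j] = dj ? (bj * bj + df0 * S0) / ::Rf_rchisq(df0 + 1.0)
                 : (df0 * S0) / ::Rf_rchisq(df0);
    }
    double sse = 0.0;
    for (int i = 0; i < n; ++i) sse += e[i] * e[i];
    s2e = (sse + dfe * Se) / ::Rf_rchisq((double)n + dfe);
    check_state(s2e, it);

    if (it > burn && (it - burn) % thin == 0) {
      ++nsamp;
      mu_sum += mu;
      s2e_sum += s2e;
      for (int j = 0; j < p; ++j) {
        beta_sum[j] += beta[j];
        incl_sum[j] += delta[j];
      }
    }
    if (it % 256 == 0) Rcpp::checkUserInterrupt();
  }
  for (int j = 0; j < p; ++j) {
    beta_sum[j] /= nsamp;
    incl_sum[j] /= nsamp;
  }
  return List::create(_["mu"] = mu_sum / nsamp, _["effects"] = beta_sum,
                      _["sigma2e"] = s2e_sum / nsamp,
                      _["inclusion"] = incl_sum, _["n_samples"] = nsamp);
}

// Bayesian Lasso via the exponential scale mixture (Park & Casella):
// beta_j ~ N(0, s2e * tau2_j), tau2_j ~ Exp(lambda2 / 2),
// lambda2 ~ Gamma(shape_r, rate_d)
// [[Rcpp::export]]
List blasso_cpp(NumericMatrix X, NumericVector y, int niter, int burn,
                int thin, double dfe, double Se, double shape_r,
                double rate_d) {
  int n = X.nrow(), p = X.ncol();
  std::vector<double> xtx(p), beta(p, 0.0), invtau2(p, 1.0);
  for (int j = 0; j < p; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += X(i, j) * X(i, j);
    xtx[j] = s;
  }
  double mu = mean(y);
  std::vector<double> e(n);
  for (int i = 0; i < n; ++i) e[i] = y[i] - mu;
  double s2e = var(y) / 2.0 + 1e-8;
  double lambda2 = 1.0;

  NumericVector beta_sum(p);
  double mu_sum = 0.0, s2e_sum = 0.0, lam_sum = 0.0;
  int nsamp = 0;

  for (int it = 1; it <= niter; ++it) {
    double ebar = 0.0;
    for (int i = 0; i < n; ++i) ebar += e[i];
    ebar /= n;
    double mu_new = ::Rf_rnorm(mu + ebar, std::sqrt(s2e / n));
    for (int i = 0; i < n; ++i) e[i] += mu - mu_new;
    mu = mu_new;

    double sum_tau2 = 0.0, sum_b2_invtau2 = 0.0;
    for (int j = 0; j < p; ++j) {
      if (xtx[j] <= 0.0) continue;
      double rhs = xtx[j] * beta[j];
      for (int i = 0; i < n; ++i) rhs += X(i, j) * e[i];
      double cj = xtx[j] + invtau2[j];
      double bj = ::Rf_rnorm(rhs / cj, std::sqrt(s2e / cj));
      double d = beta[j] - bj;
      if (d != 0.0) for (int i = 0; i < n; ++i) e[i] += X(i, j) * d;
      beta[j] = bj;
      double b2 = bj * bj;
      if (b2 < 1e-12) b2 = 1e-12;
      invtau2[j] = rinvgauss1(std::sqrt(lambda2 * s2e / b2), lambda2);
      sum_tau2 += 1.0 / invtau2[j];
      sum_b2_invtau2 += bj * bj * invtau2[j];
    }
    lambda2 = ::Rf_rgamma(p + shape_r, 1.0 / (sum_tau2 / 2.0 + rate_d));
    double sse = 0.0;
    for (int i = 0; i < n; ++i) sse += e[i] * e[i];
    s2e = (sse + sum_b2_invtau2 + dfe * Se) /
          ::Rf_rchisq((double)n + (double)p + dfe);
    check_state(s2e, it);

    if (it > burn && (it - burn) % thin == 0) {
      ++nsamp;
      mu_sum += mu;
      s2e_sum += s2e;
      lam_sum += std::sqrt(lambda2);
      for (int j = 0; j < p; ++j) beta_sum[j] += beta[j];
    }
    if (it % 256 == 0) Rcpp::checkUserInterrupt();
  }
  for (int j = 0; j < p; ++j) beta_sum[j] /= nsamp;
  return List::create(_["mu"] = mu_sum / nsamp, _["effects"] = beta_sum,
                      _["sigma2e"] = s2e_sum / nsamp,
                      _["lambda"] = lam_sum / nsamp,
                      _["n_samples"] = nsamp);
}
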