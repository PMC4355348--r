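#include <Rcpp.h>
using namespace Rcpp;

// Scaled inverse chi-square draw: nu * S / chisq(nu)
static inline double rscinv(double nu, double S) {
  return nu * S / R::rchisq(nu);
}

// Gibbs sampler for whole-genome regression with per-marker effect
// variances (scaled-inverse-chi-square prior) and, for the mixture
// variant, a point mass at zero with prior probability pi. The inclusion
// indicator is sampled from the marginal likelihood with the effect
// integrated out. X and y are expected centered; the residual intercept
// is sampled as well. Uses R's RNG, so set.seed() makes chains
// reproducible.
//
// variant: 0 = all markers in the model ("Bayes A"),
//          1 = mixture with point mass at zero ("Bayes B")
// [[Rcpp::export(name = ".gibbs_bayes")]]
List gibbs_bayes(const NumericMatrix& X, const NumericVector& y,
                 double nu, double S, double pi_zero,
                 int n_iter, int burn_in, int thin, int variant,
                 double nu_e, double S_e) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<double> u(p, 0.0), su2(p, 0.0), xx(p, 0.0);
  std::vector<int> incl(p, 1);
  std::vector<double> u_sum(p, 0.0), incl_sum(p, 0.0);
  double mu = 0.0, mu_sum = 0.0, se2_sum = 0.0;
  int n_kept = 0;

  for (int j = 0; j < p; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += X(i, j) * X(i, j);
    xx[j] = s;
    su2[j] = rscinv(nu, S);
  }
  std::vector<double> e(y.begin(), y.end());
  double se2 = 0.0;
  for (int i = 0; i < n; ++i) se2 += e[i] * e[i];
  se2 = se2 / n / 2.0 + 1e-8;

  const double log_prior_odds =
      (variant == 1) ? std::log((1.0 - pi_zero) / std::max(pi_zero, 1e-300)) : 0.0;

  for (int it = 0; it < n_iter; ++it) {
    // intercept on the centered data
    double ebar = 0.0;
    for (int i = 0; i < n; ++i) ebar += e[i] + mu;
    ebar /= n;
    double mu_new = R::rnorm(ebar, std::sqrt(se2 / n));
    for (int i = 0; i < n; ++i) e[i] += mu - mu_new;
    mu = mu_new;

    for (int j = 0; j < p; ++j) {
      if (xx[j] <= 0.0) { u[j] = 0.0; continue; }
      // remove marker j from the residual
      double rhs = 0.0;
      if (u[j] != 0.0) {
        for (int i = 0; i < n; ++i) { e[i] += X(i, j) * u[j]; rhs += X(i, j) * e[i]; }
      } else {
        for (int i = 0; i < n; ++i) rhs += X(i, j) * e[i];
      }
      bool take = true;
      if (variant == 1) {
        // marginal log-odds of inclusion with the effect integrated out
        double v = se2 + xx[j] * su2[j];
        double lo = log_prior_odds + 0.5 * std::log(se2 / v) +
                    rhs * rhs * su2[j] / (2.0 * se2 * v);
        double pr = 1.0 / (1.0 + std::exp(-lo));
        take = (R::unif_rand() < pr);
        incl[j] = take ? 1 : 0;
      }
      if (take) {
        double c = xx[j] + se2 / su2[j];
        double mean = rhs / c;
        u[j] = R::rnorm(mean, std::sqrt(se2 / c));
        for (int i = 0; i < n; ++i) e[i] -= X(i, j) * u[j];
        su2[j] = rscinv(nu + 1.0, (nu * S + u[j] * u[j]) / (nu + 1.0));
      } else {
        u[j] = 0.0;
        su2[j] = rscinv(nu, S);   // refresh from the prior
      }
    }
    double sse = 0.0;
    for (int i = 0; i < n; ++i) sse += e[i] * e[i];
    se2 = rscinv(n + nu_e, (sse + nu_e * S_e) / (n + nu_e));

    if (it >= burn_in && ((it - burn_in) % thin == 0)) {
      ++n_kept;
      for (int j = 0; j < p; ++j) { u_sum[j] += u[j]; incl_sum[j] += incl[j]; }
      mu_sum += mu;
      se2_sum += se2;
    }
  }
  NumericVector u_mean(p), incl_prob(p);
  for (int j = 0; j < p; ++j) {
    u_mean[j] = u_sum[j] / n_kept;
    incl_prob[j] = incl_sum[j] / n_kept;
  }
  return List::create(_["u_mean"] = u_mean,
                      _["mu_mean"] = mu_sum / n_kept,
                      _["sigma_e2_mean"] = se2_sum / n_kept,
                      _["incl_prob"] = incl_prob,
                      _["n_kept"] = n_kept);
}
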