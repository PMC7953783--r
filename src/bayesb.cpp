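#include <Rcpp.h>
using namespace Rcpp;

// Gibbs sampler for the Bayes B mixture regression:
//   y = mu + X beta + e,  beta_j = 0 with probability pi0, otherwise
//   beta_j | sigma2_j ~ N(0, sigma2_j), sigma2_j ~ scaled-inv-chi2(df_b, S_b)
//   (marginally a scaled-t effect), e ~ N(0, sigma2_e I),
//   sigma2_e ~ scaled-inv-chi2(df_e, S_e).
// Inclusion odds use the marginal likelihood with beta_j integrated out given
// sigma2_j. Uses R's RNG, so set.seed() on the R side fixes the chain.
// [[Rcpp::export]]
List bayesb_gibbs_cpp(const NumericMatrix X, const NumericVector y,
                      const int niter, const int burnin, const int thin,
                      const double pi0, const double df_b, const double S_b,
                      const double df_e, const double S_e) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<double> xx(p);
  for (int j = 0; j < p; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += X(i, j) * X(i, j);
    xx[j] = s;
  }
  double ybar = 0.0;
  for (int i = 0; i < n; ++i) ybar += y[i];
  ybar /= n;

  double mu = ybar;
  std::vector<double> beta(p, 0.0), s2j(p, S_b > 0 ? S_b : 1e-8);
  std::vector<bool> delta(p, false);
  std::vector<double> e(n);
  double ss0 = 0.0;
  for (int i = 0; i < n; ++i) { e[i] = y[i] - mu; ss0 += e[i] * e[i]; }
  double s2e = std::max(ss0 / n, 1e-12);

  std::vector<double> beta_sum(p, 0.0), incl_sum(p, 0.0);
  double mu_sum = 0.0, s2e_sum = 0.0;
  int nsamp = 0;
  const double logit_prior =
      (pi0 <= 0.0) ? R_PosInf : (pi0 >= 1.0) ? R_NegInf
                              : std::log(1.0 - pi0) - std::log(pi0);

  for (int it = 0; it < niter; ++it) {
    // intercept
    double esum = 0.0;
    for (int i = 0; i < n; ++i) esum += e[i];
    double mu_new = mu + esum / n + norm_rand() * std::sqrt(s2e / n);
    double dmu = mu_new - mu;
    for (int i = 0; i < n; ++i) e[i] -= dmu;
    mu = mu_new;

    for (int j = 0; j < p; ++j) {
      if (xx[j] <= 0.0) continue;
      const double* xj = &X(0, j);
      const double b_old = beta[j];
      // per-marker variance: posterior if included last round, prior draw else
      if (delta[j]) {
        s2j[j] = (df_b * S_b + b_old * b_old) / Rf_rchisq(df_b + 1.0);
      } else {
        s2j[j] = df_b * S_b / Rf_rchisq(df_b);
      }
      // right-hand side against the residual with marker j removed:
      // rhs = x_j' (e + x_j b_old) = x_j'e + xx_j b_old  (single pass)
      double rhs = 0.0;
      for (int i = 0; i < n; ++i) rhs += xj[i] * e[i];
      rhs += xx[j] * b_old;
      const double v = xx[j] * s2j[j] + s2e;
      const double logBF = 0.5 * (std::log(s2e / v) +
                                  rhs * rhs * s2j[j] / (std::max(s2e, 1e-300) * v));
      double p1;
      if (!R_finite(logit_prior)) {
        p1 = (logit_prior > 0) ? 1.0 : 0.0;
      } else {
        const double lo = logit_prior + logBF;
        p1 = 1.0 / (1.0 + std::exp(-lo));
      }
      double b_new = 0.0;
      if (unif_rand() < p1) {
        const double cj = xx[j] + s2e / s2j[j];
        b_new = rhs / cj + norm_rand() * std::sqrt(s2e / cj);
        delta[j] = true;
      } else {
        delta[j] = false;
      }
      beta[j] = b_new;
      if (b_new != b_old) {
        const double db = b_old - b_new;
        for (int i = 0; i < n; ++i) e[i] += xj[i] * db;
      }
    }
    double sse = 0.0;
    for (int i = 0; i < n; ++i) sse += e[i] * e[i];
    s2e = std::max((df_e * S_e + sse) / Rf_rchisq(df_e + n), 1e-300);

    if (it >= burnin && (it - burnin) % thin == 0) {
      ++nsamp;
      mu_sum += mu;
      s2e_sum += s2e;
      for (int j = 0; j < p; ++j) {
        if (delta[j]) {
          beta_sum[j] += beta[j];
          incl_sum[j] += 1.0;
        }
      }
    }
  }
  NumericVector bhat(p), prob(p);
  for (int j = 0; j < p; ++j) {
    bhat[j] = beta_sum[j] / nsamp;
    prob[j] = incl_sum[j] / nsamp;
  }
  return List::create(_["mu"] = mu_sum / nsamp,
                      _["beta"] = bhat,
                      _["inclusion_prob"] = prob,
                      _["sigma2e"] = s2e_sum / nsamp,
                      _["n_samples"] = nsamp);
}
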