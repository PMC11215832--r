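#include <Rcpp.h>
using namespace Rcpp;

// Single-site Gibbs sampler for stochastic-search variable selection
// regressions of the BayesB / BayesCpi family:
//   y = 1 mu + sum_j x_j beta_j delta_j + e,  e ~ N(0, sigma2_e I)
//   P(delta_j = 0) = pi
//   BayesB:   beta_j | s2b_j ~ N(0, s2b_j), s2b_j ~ scaled-inv-chi2(df_v, S2)
//             (marginally t-distributed effects), pi fixed
//   BayesCpi: beta_j ~ N(0, s2b) common, s2b ~ scaled-inv-chi2(df_v, S2),
//             pi ~ Uniform(0,1) updated as Beta(#null + 1, #nonnull + 1)
//
// Uses R's RNG (RNGScope via Rcpp export) so set.seed() governs the chain.

// [[Rcpp::export(name = ".gibbs_ssvs")]]
List gibbs_ssvs(const NumericMatrix& X, const NumericVector& y,
                int n_iter, int burn_in, int thin,
                double pi0, bool update_pi, bool common_var,
                double df_v, double scale_S2,
                bool update_mu, bool update_sigma_e,
                double sigma_e2_init, double nu_e, double Se2,
                bool fix_sigma_beta, double sigma_beta_fixed) {
  const int n = X.nrow(), J = X.ncol();
  if (burn_in >= n_iter) stop("burn-in must be shorter than the chain");

  NumericVector xx(J);
  for (int j = 0; j < J; ++j) {
    double s = 0.0;
    const double* xj = &X(0, j);
    for (int i = 0; i < n; ++i) s += xj[i] * xj[i];
    xx[j] = s;
  }

  NumericVector beta(J, 0.0);
  std::vector<int> delta(J, 0);
  double prior_mean_s2b = (df_v > 2.0) ? df_v * scale_S2 / (df_v - 2.0) : scale_S2;
  NumericVector s2b(J, prior_mean_s2b);
  double s2b_c = fix_sigma_beta ? sigma_beta_fixed : prior_mean_s2b;
  if (fix_sigma_beta) std::fill(s2b.begin(), s2b.end(), sigma_beta_fixed);
  double mu = update_mu ? Rcpp::mean(y) : 0.0;
  double sig2e = sigma_e2_init, pi = pi0;

  NumericVector r(n);
  for (int i = 0; i < n; ++i) r[i] = y[i] - mu;

  const int n_keep = (n_iter - burn_in + thin - 1) / thin;
  NumericVector sumb(J, 0.0), sumb2(J, 0.0), incl(J, 0.0);
  NumericVector pi_samples(update_pi ? n_keep : 0);
  double sum_mu = 0.0, sum_sig2e = 0.0;
  int kept = 0;

  for (int it = 0; it < n_iter; ++it) {
    int m_incl = 0;
    double ssb = 0.0;
    for (int j = 0; j < J; ++j) {
      const double* xj = &X(0, j);
      double bold = delta[j] ? beta[j] : 0.0;
      double rhs = 0.0;
      for (int i = 0; i < n; ++i) rhs += xj[i] * r[i];
      rhs += xx[j] * bold;
      double s2 = common_var ? s2b_c : s2b[j];
      double c = xx[j] * s2 + sig2e;
      double logodds = std::log(1.0 - pi) - std::log(pi)
        - 0.5 * std::log(c / sig2e) + 0.5 * rhs * rhs * s2 / (sig2e * c);
      int dnew = (unif_rand() < 1.0 / (1.0 + std::exp(-logodds))) ? 1 : 0;
      double bnew = 0.0;
      if (dnew) {
        double prec = xx[j] + sig2e / s2;
        bnew = rhs / prec + std::sqrt(sig2e / prec) * norm_rand();
      }
      if (bnew != bold) {
        double d = bnew - bold;
        for (int i = 0; i < n; ++i) r[i] -= xj[i] * d;
      }
      beta[j] = bnew; delta[j] = dnew;
      if (dnew) { ++m_incl; ssb += bnew * bnew; }
      if (!common_var && !fix_sigma_beta) {
        s2b[j] = dnew
          ? (df_v * scale_S2 + bnew * bnew) / R::rchisq(df_v + 1.0)
          : df_v * scale_S2 / R::rchisq(df_v);
      }
    }
    if (common_var && !fix_sigma_beta)
      s2b_c = (df_v * scale_S2 + ssb) / R::rchisq(df_v + m_incl);
    if (update_pi)
      pi = R::rbeta((double)(J - m_incl) + 1.0, (double)m_incl + 1.0);
    if (update_mu) {
      double rbar = Rcpp::mean(r);
      double d = rbar + std::sqrt(sig2e / n) * norm_rand();
      mu += d;
      for (int i = 0; i < n; ++i) r[i] -= d;
    }
    if (update_sigma_e) {
      double rss = 0.0;
      for (int i = 0; i < n; ++i) rss += r[i] * r[i];
      sig2e = (rss + nu_e * Se2) / R::rchisq((double)n + nu_e);
    }
    if (!R_finite(sig2e) || !R_finite(beta[0]))
      stop("non-finite sampler state at iteration %d", it + 1);

    if (it >= burn_in && (it - burn_in) % thin == 0) {
      for (int j = 0; j < J; ++j) {
        double eff = delta[j] ? beta[j] : 0.0;
        sumb[j] += eff; sumb2[j] += eff * eff; incl[j] += delta[j];
      }
      if (update_pi) pi_samples[kept] = pi;
      sum_mu += mu; sum_sig2e += sig2e;
      ++kept;
    }
  }

  NumericVector beta_mean(J), beta_sd(J), incl_freq(J);
  for (int j = 0; j < J; ++j) {
    beta_mean[j] = sumb[j] / kept;
    double var = (sumb2[j] - kept * beta_mean[j] * beta_mean[j])
      / std::max(kept - 1, 1);
    beta_sd[j] = std::sqrt(std::max(var, 0.0));
    incl_freq[j] = incl[j] / kept;
  }

  return List::create(
    _["beta_mean"] = beta_mean, _["beta_se"] = beta_sd,
    _["incl_freq"] = incl_freq, _["pi_samples"] = pi_samples,
    _["mu_mean"] = sum_mu / kept, _["sigma_e_mean"] = sum_sig2e / kept,
    _["n_samples"] = kept);
}
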