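#include <Rcpp.h>
using namespace Rcpp;

// Mean-field coordinate ascent for the sparse K-mixture regression
//   y = X beta + e,  e ~ N(0, tau2 I)
//   beta_j ~ pi * sum_k eta_k N(0, sigma2_k) + (1 - pi) delta0
// with variational family
//   q(beta_j) = sum_k alpha_jk N(mu_jk, s2_jk) + (1 - sum_k alpha_jk) delta0.
//
// Residual bookkeeping: if XtX (J x J) is supplied we maintain q = X'r and a
// per-SNP update costs O(J); otherwise we maintain r itself at O(n) per SNP.
// Hyperparameters (eta, sigma2, tau2) get closed-form EM updates after each
// sweep; every block update maximizes the ELBO given the rest, so the ELBO
// trace is non-decreasing up to rounding.

static inline double dot_col(const NumericMatrix& X, int j, const NumericVector& v) {
  const double* xj = &X(0, j);
  double s = 0.0;
  int n = X.nrow();
  for (int i = 0; i < n; ++i) s += xj[i] * v[i];
  return s;
}

// [[Rcpp::export(name = ".vb_mix_fit")]]
List vb_mix_fit(const NumericMatrix& X, const NumericVector& y,
                NumericVector sigma2, NumericVector eta, double pi_incl,
                double tau2, const NumericMatrix& alpha0,
                const NumericMatrix& mu0, double tol, int maxit,
                bool update_sigma, bool update_eta, bool update_tau,
                double sigma_min, Nullable<NumericMatrix> XtX_) {
  const int n = X.nrow(), J = X.ncol(), K = sigma2.size();
  const bool usextx = XtX_.isNotNull();
  NumericMatrix XtX;
  if (usextx) XtX = NumericMatrix(XtX_);

  NumericMatrix alpha(clone(alpha0)), mu(clone(mu0)), s2(J, K);
  NumericVector xx(J), xty(J), m(J), v(J);
  double yty = 0.0;
  for (int i = 0; i < n; ++i) yty += y[i] * y[i];
  for (int j = 0; j < J; ++j) {
    double sxx = 0.0, sxy = 0.0;
    const double* xj = &X(0, j);
    for (int i = 0; i < n; ++i) { sxx += xj[i] * xj[i]; sxy += xj[i] * y[i]; }
    xx[j] = sxx; xty[j] = sxy;
    double mj = 0.0, vj = 0.0;
    for (int k = 0; k < K; ++k) {
      s2[j + (R_xlen_t)J * k] = sigma2[k];
      mj += alpha(j, k) * mu(j, k);
      vj += alpha(j, k) * (mu(j, k) * mu(j, k) + sigma2[k]);
    }
    m[j] = mj; v[j] = vj;
  }

  // residual bookkeeping
  NumericVector r(n), q(J);
  if (usextx) {
    for (int j = 0; j < J; ++j) {
      double s = xty[j];
      const double* gj = &XtX(0, j);
      for (int l = 0; l < J; ++l) s -= gj[l] * m[l];
      q[j] = s;
    }
  } else {
    for (int i = 0; i < n; ++i) r[i] = y[i];
    for (int j = 0; j < J; ++j) {
      if (m[j] != 0.0) {
        const double* xj = &X(0, j);
        for (int i = 0; i < n; ++i) r[i] -= xj[i] * m[j];
      }
    }
  }

  const double log_spike = (pi_incl < 1.0) ? std::log(1.0 - pi_incl) : R_NegInf;
  std::vector<double> logw(K + 1), sjk(K), mjk(K);
  NumericVector elbo_trace(maxit);
  bool converged = false;
  double elbo_prev = R_NegInf;
  int it = 0;

  for (it = 0; it < maxit; ++it) {
    // --- coordinate sweep over SNPs ---
    for (int j = 0; j < J; ++j) {
      double rhs = (usextx ? q[j] : dot_col(X, j, r)) + xx[j] * m[j];
      double maxlw = log_spike;
      for (int k = 0; k < K; ++k) {
        double s2k = tau2 * sigma2[k] / (sigma2[k] * xx[j] + tau2);
        double muk = rhs * s2k / tau2;
        sjk[k] = s2k; mjk[k] = muk;
        double lw = (eta[k] > 0.0 && pi_incl > 0.0)
          ? std::log(pi_incl * eta[k]) + 0.5 * std::log(s2k / sigma2[k])
            + 0.5 * muk * muk / s2k
          : R_NegInf;
        logw[k] = lw;
        if (lw > maxlw) maxlw = lw;
      }
      logw[K] = log_spike;
      // maxlw is always finite: either the spike (pi < 1) or a slab (pi = 1)
      double z = 0.0;
      for (int k = 0; k <= K; ++k) {
        logw[k] = std::exp(logw[k] - maxlw);  // exp(-Inf) = 0
        z += logw[k];
      }
      double mnew = 0.0, vnew = 0.0;
      for (int k = 0; k < K; ++k) {
        double a = logw[k] / z;
        alpha(j, k) = a; mu(j, k) = mjk[k]; s2(j, k) = sjk[k];
        mnew += a * mjk[k];
        vnew += a * (mjk[k] * mjk[k] + sjk[k]);
      }
      double dlt = m[j] - mnew;
      if (dlt != 0.0) {
        if (usextx) {
          const double* gj = &XtX(0, j);
          for (int l = 0; l < J; ++l) q[l] += gj[l] * dlt;
        } else {
          const double* xj = &X(0, j);
          for (int i = 0; i < n; ++i) r[i] += xj[i] * dlt;
        }
      }
      m[j] = mnew; v[j] = vnew;
    }

    // periodic exact recomputation against drift (q path only)
    if (usextx && (it + 1) % 50 == 0) {
      for (int j = 0; j < J; ++j) {
        double s = xty[j];
        const double* gj = &XtX(0, j);
        for (int l = 0; l < J; ++l) s -= gj[l] * m[l];
        q[j] = s;
      }
    }

    // --- EM updates of mixture hyperparameters ---
    if (update_sigma || update_eta) {
      double tot = 0.0;
      for (int k = 0; k < K; ++k) {
        double sk = 0.0, ssq = 0.0;
        for (int j = 0; j < J; ++j) {
          sk += alpha(j, k);
          ssq += alpha(j, k) * (mu(j, k) * mu(j, k) + s2(j, k));
        }
        if (update_sigma && sk > 1e-10) {
          // Floor guards against slab collapse (sigma2 -> 0 makes inclusion
          // free and leaves pi unidentified); a constrained block maximum
          // keeps the ELBO non-decreasing.
          sigma2[k] = std::max(ssq / sk, sigma_min);
        }
        if (update_eta) eta[k] = sk;
        tot += sk;
      }
      if (update_eta) {
        if (tot > 1e-12) { for (int k = 0; k < K; ++k) eta[k] /= tot; }
        else { for (int k = 0; k < K; ++k) eta[k] = 1.0 / K; }
      }
    }

    // residual sum of squares and quadratic correction
    double rss;
    if (usextx) {
      double qm = 0.0, xym = 0.0;
      for (int j = 0; j < J; ++j) { qm += q[j] * m[j]; xym += xty[j] * m[j]; }
      rss = yty - xym - qm;
      if (rss < 0.0) rss = 0.0;
    } else {
      rss = 0.0;
      for (int i = 0; i < n; ++i) rss += r[i] * r[i];
    }
    double corr = 0.0;
    for (int j = 0; j < J; ++j) corr += xx[j] * (v[j] - m[j] * m[j]);

    if (update_tau) tau2 = (rss + corr) / n;

    // --- ELBO ---
    double elbo = -0.5 * n * std::log(2.0 * M_PI * tau2)
      - (rss + corr) / (2.0 * tau2);
    for (int j = 0; j < J; ++j) {
      double asum = 0.0;
      for (int k = 0; k < K; ++k) {
        double a = alpha(j, k);
        asum += a;
        if (a > 1e-300) {
          elbo += a * (std::log(pi_incl * eta[k]) - std::log(a)
                       + 0.5 * (1.0 + std::log(s2(j, k) / sigma2[k])
                                - (s2(j, k) + mu(j, k) * mu(j, k)) / sigma2[k]));
        }
      }
      double a0 = 1.0 - asum;
      if (a0 > 1e-300 && pi_incl < 1.0) elbo += a0 * (log_spike - std::log(a0));
    }
    if (!R_finite(elbo))
      stop("non-finite evidence lower bound at iteration %d", it + 1);
    elbo_trace[it] = elbo;
    if (it > 0 && std::fabs(elbo - elbo_prev) < tol) { converged = true; ++it; break; }
    elbo_prev = elbo;
  }

  return List::create(
    _["alpha"] = alpha, _["mu"] = mu, _["s2"] = s2,
    _["eta"] = eta, _["sigma2"] = sigma2, _["tau2"] = tau2,
    _["beta"] = m, _["elbo"] = elbo_trace[Range(0, std::max(it - 1, 0))],
    _["converged"] = converged, _["n_iter"] = it);
}
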