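# Reference implementations used as oracles: numerical-integration posteriors
# for single-predictor spike-and-slab models and dense mixed-model solvers
# for GBLUP. These are deliberately slow and direct.

# Density of a scaled inverse chi-square distribution with df degrees of
# freedom and scale parameter `scale` (mode near scale for large df).
dsinvchisq <- function(s, df, scale) {
  a <- df / 2
  exp(a * log(a * scale) - lgamma(a) - (a + 1) * log(s) - a * scale / s)
}

# Exact posterior for a single-predictor regression y = x b + e,
# e ~ N(0, tau2 I), b ~ (1 - pi) delta0 + pi sum_k eta_k N(0, sigma2_k),
# by numerical integration over b. Returns E[b | y] and P(b != 0 | y).
oracle_mix_single <- function(x, y, pi_incl, eta, sigma2, tau2) {
  xx <- sum(x^2)
  xy <- sum(x * y)
  # likelihood ratio to b = 0, analytic in b
  lr <- function(b) exp((2 * b * xy - b^2 * xx) / (2 * tau2))
  K <- length(sigma2)
  m <- num <- numeric(K)
  for (k in seq_len(K)) {
    sdk <- sqrt(sigma2[k])
    m[k] <- integrate(function(b) lr(b) * dnorm(b, 0, sdk),
                      -Inf, Inf, rel.tol = 1e-10)$value
    num[k] <- integrate(function(b) b * lr(b) * dnorm(b, 0, sdk),
                        -Inf, Inf, rel.tol = 1e-10)$value
  }
  norm <- (1 - pi_incl) + pi_incl * sum(eta * m)
  list(
    beta = pi_incl * sum(eta * num) / norm,
    pip = pi_incl * sum(eta * m) / norm
  )
}

# Exact posterior for a single-predictor BayesB model with fixed residual
# variance and zero intercept: b | s ~ N(0, s) when included,
# s ~ scaled-inv-chisq(df_v, S2), prior exclusion probability pi_null.
# Integrates the conjugate conditional results over the variance prior.
oracle_bayesb_single <- function(x, y, pi_null, df_v, S2, sigma_e2) {
  xx <- sum(x^2)
  xy <- sum(x * y)
  # Bayes factor slab vs null and conditional posterior mean, given s
  bf <- function(s) {
    sqrt(sigma_e2 / (xx * s + sigma_e2)) *
      exp(xy^2 * s / (2 * sigma_e2 * (xx * s + sigma_e2)))
  }
  bpost <- function(s) xy * s / (xx * s + sigma_e2)
  m1 <- integrate(function(s) bf(s) * dsinvchisq(s, df_v, S2),
                  0, Inf, rel.tol = 1e-10)$value
  num <- integrate(function(s) bf(s) * bpost(s) * dsinvchisq(s, df_v, S2),
                   0, Inf, rel.tol = 1e-10)$value
  norm <- pi_null + (1 - pi_null) * m1
  list(
    beta = (1 - pi_null) * num / norm,
    pip = (1 - pi_null) * m1 / norm
  )
}

# Dense mixed-model-equation solve for y = 1 mu + g + e with
# g ~ N(0, sg2 G), e ~ N(0, se2 D). Returns the GLS intercept and the BLUP
# of g from the standard Henderson equations.
oracle_gblup_mme <- function(y, G, D_diag, sg2, se2) {
  n <- length(y)
  Ri <- diag(1 / (se2 * D_diag), n)
  Gi <- solve(sg2 * G)
  C <- rbind(
    cbind(sum(1 / (se2 * D_diag)), matrix(colSums(Ri), 1)),
    cbind(matrix(rowSums(Ri), n), Ri + Gi)
  )
  rhs <- c(sum(y / (se2 * D_diag)), drop(Ri %*% y))
  sol <- unname(solve(C, rhs))
  list(mu = sol[1], gebv = sol[-1])
}

# Direct GLS quantities from the marginal covariance V = sg2 G + se2 D:
# intercept, BLUP and prediction of unobserved individuals.
oracle_gblup_gls <- function(y, G, D_diag, sg2, se2,
                             train_idx = seq_along(y) + 0L, test_idx = NULL) {
  Gtt <- G[train_idx, train_idx, drop = FALSE]
  V <- sg2 * Gtt + se2 * diag(D_diag[train_idx], length(train_idx))
  Vi <- solve(V)
  mu <- sum(Vi %*% y) / sum(Vi)
  a <- drop(Vi %*% (y - mu))
  out <- list(mu = mu, gebv = sg2 * drop(Gtt %*% a))
  if (!is.null(test_idx)) {
    out$gebv_test <- sg2 * drop(G[test_idx, train_idx, drop = FALSE] %*% a)
  }
  out
}

# Dense restricted log-likelihood of (sg2, se2), profiled over mu only, for a
# direct REML grid/optimize comparison. Constant terms are dropped the same
# way on both sides of the comparison because only the argmax is compared.
oracle_reml_dense <- function(y, G, D_diag) {
  n <- length(y)
  ones <- rep(1, n)
  ll <- function(log_gamma) {
    gam <- exp(log_gamma)
    V0 <- gam * G + diag(D_diag, n)    # V / se2
    Vi <- solve(V0)
    mu <- sum(Vi %*% y) / sum(Vi)
    rssw <- drop(crossprod(y - mu, Vi %*% (y - mu)))
    se2 <- rssw / (n - 1)
    -0.5 * ((n - 1) * log(se2) + determinant(V0)$modulus +
              log(sum(Vi)) + (n - 1))
  }
  opt <- optimize(ll, c(-12, 12), maximum = TRUE, tol = 1e-10)
  gam <- exp(opt$maximum)
  V0 <- gam * G + diag(D_diag, n)
  Vi <- solve(V0)
  mu <- sum(Vi %*% y) / sum(Vi)
  se2 <- drop(crossprod(y - mu, Vi %*% (y - mu))) / (n - 1)
  list(sigma_g_sq = gam * se2, sigma_e_sq = se2, gamma = gam)
}
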