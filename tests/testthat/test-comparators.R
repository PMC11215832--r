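test_that("build_grm matches the VanRaden formula on a hand-computed example", {
  X <- matrix(c(0, 1, 2,
                2, 1, 0), nrow = 3)
  p <- colMeans(X) / 2              # 0.5, 0.5
  W <- sweep(X, 2, 2 * p)
  denom <- 2 * sum(p * (1 - p))     # 1
  expect_equal(build_grm(X), tcrossprod(W) / denom)
  expect_error(build_grm(matrix(c(0, 0, 0, 1, 2, 1), 3)), "monomorphic")
})

test_that("the GRM diagonal averages near one on a simulated panel", {
  g <- simulate_genotypes(200, 400, seed = 1)
  G <- build_grm(g)
  expect_true(isSymmetric(G, tol = 1e-12))
  expect_equal(mean(diag(G)), 1, tolerance = 0.05)
  expect_equal(mean(G), 0, tolerance = 0.01)
})

test_that("GBLUP with fixed variance components matches the dense GLS solve", {
  set.seed(2)
  n <- 40
  g <- simulate_genotypes(n, 150, seed = 3)
  G <- build_grm(g)
  D <- runif(n, 0.3, 3)
  y <- rnorm(n)
  fit <- fit_gblup(y, G, D, reml = FALSE, sigma_g_sq = 0.4, sigma_e_sq = 0.7)
  ora <- oracle_gblup_gls(y, G, D, 0.4, 0.7)
  expect_equal(fit$mu, ora$mu, tolerance = 1e-10)
  expect_equal(fit$gebv, ora$gebv, tolerance = 1e-10)
  expect_equal(fit$h2_hat, 0.4 / 1.1)
})

test_that("predict_gblup reproduces the relationship-based BLUP extension", {
  set.seed(4)
  n <- 50
  g <- simulate_genotypes(n, 200, seed = 5)
  G <- build_grm(g)
  D <- runif(n, 0.5, 2)
  tr <- 1:40; te <- 41:50
  y <- rnorm(40)
  fit <- fit_gblup(y, G, D, reml = FALSE, train_idx = tr,
                   sigma_g_sq = 0.3, sigma_e_sq = 0.6)
  ora <- oracle_gblup_gls(y, G, D, 0.3, 0.6, train_idx = tr, test_idx = te)
  expect_equal(predict_gblup(fit, te), ora$gebv_test, tolerance = 1e-8)
})

test_that("REML finds the dense restricted-likelihood optimum", {
  set.seed(6)
  n <- 60
  g <- simulate_genotypes(n, 300, seed = 7)
  G <- build_grm(g)
  D <- runif(n, 0.5, 2)
  y <- drop(chol(0.5 * G + 0.5 * diag(D, n)) %*% rnorm(n)) + 1
  fit <- fit_gblup(y, G, D)
  ora <- oracle_reml_dense(y, G, D)
  expect_equal(fit$sigma_g_sq, ora$sigma_g_sq, tolerance = 1e-5)
  expect_equal(fit$sigma_e_sq, ora$sigma_e_sq, tolerance = 1e-5)
})

test_that("a trait with no genetic signal yields a near-zero genetic variance", {
  ok <- logical(10)
  for (s in 1:10) {
    g <- simulate_genotypes(400, 400, seed = 100 + s)
    G <- build_grm(g)
    set.seed(200 + s)
    y <- rnorm(400)
    fit <- fit_gblup(y, G)
    ok[s] <- fit$h2_hat < 0.05
  }
  expect_gte(sum(ok), 8)
})

test_that("fit_gblup validates weights and dimensions", {
  G <- diag(5)
  expect_error(fit_gblup(rnorm(5), G, D_diag = c(1, 1, 0, 1, 1)), "positive")
  expect_error(fit_gblup(rnorm(4), G), "one record per")
  expect_error(fit_gblup(rnorm(5), G, reml = FALSE), "supply sigma_g_sq")
})

test_that("bayes_config validates the chain settings and derives the prior scale", {
  expect_error(bayes_config(n_iter = 100, burn_in = 100), "burn_in")
  expect_error(bayes_config(thin = 0), "thin")
  cfg <- bayes_config()
  y <- rnorm(100)
  S2 <- banngp:::bayes_default_scale(cfg, y, 500)
  target <- cfg$h2_prior * var(y) / ((1 - cfg$pi_fixed) * 500)
  expect_equal(S2, target * (cfg$df_v - 2) / cfg$df_v)
  # prior mean of a scaled-inv-chisq(df, S2) is df S2 / (df - 2)
  expect_equal(S2 * cfg$df_v / (cfg$df_v - 2), target)
})

test_that("Gibbs chains are reproducible under a fixed seed", {
  d <- toy_signal(n = 150, J = 12, seed = 8)
  cfg <- bayes_config(n_iter = 500, burn_in = 100, thin = 2, seed = 9)
  f1 <- fit_bayesb(d$X, d$y, cfg)
  f2 <- fit_bayesb(d$X, d$y, cfg)
  expect_identical(f1$beta_mean, f2$beta_mean)
  expect_identical(f1$incl_freq, f2$incl_freq)
  f3 <- fit_bayesb(d$X, d$y, bayes_config(n_iter = 500, burn_in = 100,
                                          thin = 2, seed = 10))
  expect_false(identical(f1$beta_mean, f3$beta_mean))
})

test_that("BayesB concentrates inclusion on a strong signal", {
  d <- toy_signal(n = 1000, J = 50, j_causal = 7, seed = 11)
  cfg <- bayes_config(n_iter = 5000, burn_in = 2000, thin = 10, seed = 12)
  fit <- fit_bayesb(d$X, d$y, cfg)
  expect_gt(fit$incl_freq[7], 0.9)
  expect_lt(mean(fit$incl_freq[-7]), 0.2)
  expect_equal(fit$n_samples, 300L)
  expect_true(all(fit$incl_freq >= 0 & fit$incl_freq <= 1))
})

test_that("null traits keep BayesB inclusion at or below the prior", {
  set.seed(13)
  X <- scale(matrix(rnorm(800 * 40), 800, 40))
  y <- drop(scale(rnorm(800)))
  cfg <- bayes_config(n_iter = 4000, burn_in = 1000, thin = 5, seed = 14)
  fit <- fit_bayesb(X, y, cfg)
  # the Occam penalty of the marginal Bayes factor keeps posterior inclusion
  # below the prior mass 1 - pi for data without signal
  expect_lt(mean(fit$incl_freq), (1 - cfg$pi_fixed) + 0.02)
  expect_gt(mean(fit$incl_freq), 0)
})

test_that("BayesCpi samples pi and shares one slab variance", {
  d <- toy_signal(n = 400, J = 30, seed = 15)
  cfg <- bayes_config(n_iter = 2000, burn_in = 500, thin = 5, seed = 16)
  fit <- fit_bayescpi(d$X, d$y, cfg)
  expect_false(is.null(fit$pi_samples))
  expect_true(all(fit$pi_samples > 0 & fit$pi_samples < 1))
  expect_equal(fit$method, "bayescpi")
  held <- fit_bayescpi(d$X, d$y, cfg, update_pi = FALSE)
  expect_null(held$pi_samples)
})

test_that("bayes_fit predictions are the posterior-mean linear score", {
  d <- toy_signal(n = 200, J = 10, seed = 17)
  cfg <- bayes_config(n_iter = 800, burn_in = 200, thin = 2, seed = 18)
  fit <- fit_bayescpi(d$X, d$y, cfg)
  Xnew <- d$X[1:5, , drop = FALSE]
  expect_equal(predict(fit, Xnew),
               drop(Xnew %*% fit$beta_mean) + fit$mu_mean)
  td <- tidy(fit)
  expect_equal(nrow(td), 10L)
  gl <- glance(fit)
  expect_true(all(c("pi_mean", "mean_beta_se") %in% names(gl)))
})

test_that("random-forest grid search picks members of the grid", {
  d <- toy_signal(n = 120, J = 15, seed = 19)
  cfg <- rf_config(grid_trees = c(50, 100), grid_depth = c(3, 0),
                   inner_folds = 3, seed = 20)
  fit <- fit_rf(d$X, d$y, cfg)
  expect_true(fit$best$trees %in% cfg$grid_trees)
  expect_true(fit$best$depth %in% cfg$grid_depth)
  expect_equal(nrow(fit$grid), 4L)
  expect_equal(fit$best$cv_mse, min(fit$grid$cv_mse))
  pv <- predict(fit, d$X[1:10, , drop = FALSE])
  expect_length(pv, 10)
})

test_that("random forests do not manufacture fit from pure noise", {
  ok <- logical(10)
  for (s in 1:10) {
    set.seed(300 + s)
    X <- matrix(sample(0:2, 100 * 20, replace = TRUE), 100, 20)
    y <- rnorm(100)
    fit <- fit_rf(X, y, rf_config(grid_trees = 50, grid_depth = c(3, 0),
                                  inner_folds = 3, seed = s))
    ok[s] <- fit$best$cv_mse >= 0.9 * var(y)
  }
  expect_gte(sum(ok), 8)
})
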