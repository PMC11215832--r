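test_that("leaky_relu matches its definition", {
  expect_equal(leaky_relu(c(2, -1, 0)), c(2, -0.01, 0))
  expect_equal(leaky_relu(-3, slope = 0.2), -0.6)
  m <- matrix(c(-1, 1, -2, 2), 2)
  expect_equal(leaky_relu(m), matrix(c(-0.01, 1, -0.02, 2), 2))
})

test_that("standardize_xy centers and scales and names zero-variance columns", {
  set.seed(1)
  X <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- rnorm(20)
  std <- standardize_xy(X, y)
  expect_equal(unname(colMeans(std$X)), rep(0, 3))
  expect_equal(unname(apply(std$X, 2, sd)), rep(1, 3))
  expect_equal(mean(std$y), 0)
  expect_equal(sd(std$y), 1)
  X[, 2] <- 5
  expect_error(standardize_xy(X), "b")
  expect_error(standardize_xy(std$X, rep(1, 20)), "constant")
})

test_that("the inclusion-probability grid spans [1/p, 1] on a log scale", {
  grid <- banngp:::vb_pi_grid(100, 20)
  expect_length(grid, 20)
  expect_equal(min(grid), 1 / 100)
  expect_equal(max(grid), 1)
  spacing <- diff(log(grid))
  expect_lt(max(abs(spacing - spacing[1])), 1e-12)
})

test_that("the SNP-layer posterior honours its structural invariants", {
  d <- toy_signal(n = 400, J = 25, j_causal = 3, seed = 2)
  fit <- fit_snp_layer(d$X, d$y, vem_config(seed = 3))
  expect_s3_class(fit, "snp_layer_posterior")
  expect_true(all(rowSums(fit$alpha) <= 1 + 1e-8))
  expect_true(all(fit$alpha >= -1e-12))
  expect_equal(sum(fit$eta_theta), 1)
  expect_true(all(fit$sigma_theta_sq > 0))
  expect_gt(fit$tau_theta_sq, 0)
  # marginal means decompose over the mixture responsibilities
  expect_equal(fit$beta_theta, rowSums(fit$alpha * fit$mu), tolerance = 1e-10)
  expect_true(all(fit$pip >= 0 & fit$pip <= 1))
  expect_equal(sum(fit$grid$weight), 1)
  expect_true(fit$converged)
})

test_that("each coordinate-ascent trace is non-decreasing", {
  d <- toy_signal(n = 300, J = 15, seed = 4)
  fit <- fit_snp_layer(d$X, d$y, vem_config(seed = 5))
  for (tr in fit$elbo_traces) {
    expect_true(all(diff(tr) > -1e-6 * (1 + abs(tr[-length(tr)]))))
  }
})

test_that("a strong signal earns a high PIP and null SNPs stay low", {
  d <- toy_signal(n = 1000, J = 50, j_causal = 7, seed = 6)
  fit <- fit_snp_layer(d$X, d$y, vem_config(seed = 7))
  expect_gt(fit$pip[7], 0.95)
  expect_lt(mean(fit$pip[-7]), 0.1)
})

test_that("pure-noise traits keep mean PIPs low in both layers", {
  set.seed(8)
  pips <- gammas <- numeric(5)
  for (s in 1:5) {
    X <- scale(matrix(rnorm(500 * 50), 500, 50))
    y <- drop(scale(rnorm(500)))
    fit <- fit_snp_layer(X, y, vem_config(seed = s))
    pips[s] <- mean(fit$pip)
    setf <- fit_set_layer(X, y, vem_config(seed = s))
    gammas[s] <- mean(setf$gamma)
  }
  expect_lt(mean(pips), 0.2)
  expect_lt(mean(gammas), 0.2)
})

test_that("zero-init fits are deterministic and X'X bookkeeping matches the direct path", {
  d <- toy_signal(n = 120, J = 30, seed = 9)
  cfg <- vem_config(seed = 10, init = "zero")
  f1 <- fit_snp_layer(d$X, d$y, cfg)
  f2 <- fit_snp_layer(d$X, d$y, cfg)
  expect_identical(f1$beta_theta, f2$beta_theta)
  expect_identical(f1$grid$elbo, f2$grid$elbo)
  # J > 2n forces the residual-bookkeeping path; same model, same optimum
  dwide <- toy_signal(n = 14, J = 30, seed = 9)
  fw <- fit_snp_layer(dwide$X[, 1:30], dwide$y, cfg)
  expect_true(all(is.finite(fw$beta_theta)))
})

test_that("build_hidden_inputs applies the activation per set", {
  X <- matrix(c(1, -1, 2, 0.5, -2, 1), 3, 2)
  X <- scale(X)
  beta <- c(0.5, -0.25)
  part <- snp_set_partition(
    tibble::tibble(set_id = c("s1", "s2"), label = c("s1", "s2"),
                   kind = "window", snp_indices = list(1L, 2L)), 2)
  H <- build_hidden_inputs(beta, X, part)
  expect_equal(H[, 1], leaky_relu(X[, 1] * 0.5), ignore_attr = TRUE)
  expect_equal(H[, 2], leaky_relu(X[, 2] * -0.25), ignore_attr = TRUE)
  expect_identical(colnames(H), c("s1", "s2"))
  expect_error(build_hidden_inputs(c(1, 2, 3), X, part), "length")
})

test_that("fit_banns wires both layers together and predicts on the training scale", {
  g <- simulate_genotypes(300, 60, seed = 11)
  part <- partition_by_window(g$variants, window_bp = 300000)
  sim <- simulate_phenotypes(g, part, sim_architecture(pi_causal = 0.2, seed = 12))
  fit <- fit_banns(g$dosages, sim$phenotype, part, vem_config(seed = 13))
  expect_s3_class(fit, "bann_fit")
  expect_equal(length(fit$snp_layer$beta_theta), 60L)
  # prediction on the training data reproduces the stored fitted values
  expect_equal(predict(fit, g$dosages), fit$fitted, tolerance = 1e-12)
  expect_error(predict(fit, g$dosages[, 1:10]), "match")
  expect_output(print(fit), "bann_fit")
})

test_that("posterior inclusion probabilities cover both layers and stay in [0, 1]", {
  g <- simulate_genotypes(200, 40, seed = 14)
  part <- partition_by_window(g$variants, window_bp = 250000)
  sim <- simulate_phenotypes(g, part, sim_architecture(pi_causal = 0.2, seed = 15))
  fit <- fit_banns(g$dosages, sim$phenotype, part, vem_config(seed = 16))
  pip <- posterior_inclusion_probabilities(fit)
  expect_equal(nrow(pip), 40L + part$G)
  expect_true(all(pip$pip >= 0 & pip$pip <= 1))
  expect_setequal(unique(pip$layer), c("snp", "set"))
})

test_that("variance-explained estimates are proportions and reuse training data by default", {
  g <- simulate_genotypes(250, 50, seed = 17)
  part <- partition_by_window(g$variants, window_bp = 250000)
  sim <- simulate_phenotypes(g, part, sim_architecture(pi_causal = 0.3, seed = 18))
  fit <- fit_banns(g$dosages, sim$phenotype, part, vem_config(seed = 19))
  pve <- estimate_pve(fit)
  expect_gte(pve$pve_snp, 0); expect_lte(pve$pve_snp, 1)
  expect_gte(pve$pve_set, 0); expect_lte(pve$pve_set, 1)
  std <- standardize_xy(g$dosages)
  pve2 <- estimate_pve(fit, std$X)
  expect_equal(pve2$pve_snp, pve$pve_snp, tolerance = 1e-10)
  expect_equal(pve2$pve_set, pve$pve_set, tolerance = 1e-10)
})

test_that("tidy and glance summarise a network fit", {
  g <- simulate_genotypes(150, 30, seed = 20)
  part <- partition_by_window(g$variants, window_bp = 250000)
  sim <- simulate_phenotypes(g, part, sim_architecture(pi_causal = 0.3, seed = 21))
  fit <- fit_banns(g$dosages, sim$phenotype, part, vem_config(seed = 22))
  td <- tidy(fit)
  expect_equal(nrow(td), 30L + part$G)
  expect_true(all(c("layer", "term", "estimate", "pip") %in% names(td)))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1L)
  expect_true(all(c("pve_snp", "pve_set", "pi_theta", "pi_w") %in% names(gl)))
})

test_that("vem_config rejects invalid settings", {
  expect_error(vem_config(K = 0), "K")
  expect_error(vem_config(elbo_tol = 0), "elbo_tol")
  expect_error(vem_config(max_iter = 0), "max_iter")
})
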