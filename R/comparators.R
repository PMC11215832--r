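# Reference predictors: GBLUP with reliability-weighted residuals (profiled
# REML on the eigenbasis of the whitened genomic relationship matrix),
# BayesB and BayesCpi single-site Gibbs samplers, and a random-forest
# regression tuned by inner cross-validated grid search.

#' Genomic relationship matrix (VanRaden method 1)
#'
#' `G = W W' / (2 * sum(p_j (1 - p_j)))` with `W` the dosage matrix centered
#' at twice the allele-b frequency. Under this scaling the mean diagonal of
#' unrelated individuals is close to 1.
#'
#' @param X dosage matrix or [genotype_matrix()], post-QC, no missing values.
#' @param freq_b optional allele-b frequencies (defaults to the sample
#'   frequencies of `X`).
#' @return n x n symmetric matrix.
#' @export
build_grm <- function(X, freq_b = NULL) {
  if (inherits(X, "genotype_matrix")) X <- X$dosages
  if (anyNA(X)) abort("missing genotypes: run QC/imputation first")
  p <- freq_b %||% (colMeans(X) / 2)
  if (any(p <= 0 | p >= 1)) {
    abort("monomorphic SNP encountered: filter with apply_qc() first")
  }
  W <- sweep(X, 2, 2 * p)
  tcrossprod(W) / (2 * sum(p * (1 - p)))
}

#' Fit GBLUP with reliability-weighted residuals
#'
#' Model `y = 1 mu + g + e` with `g ~ N(0, G sigma_g^2)` and
#' `e ~ N(0, D sigma_e^2)`, `d_ii = (1 - r2_i) / r2_i` from the DRP
#' reliabilities. After whitening by `D^{-1/2}` the covariance is
#' `sigma_g^2 Gw + sigma_e^2 I`, so one eigendecomposition of `Gw` makes the
#' restricted likelihood a cheap 1-D function of the variance ratio, which is
#' maximized numerically (profiled REML).
#'
#' @param y response vector (standardized DRPs) for the individuals in
#'   `train_idx`.
#' @param G_mat genomic relationship matrix covering at least the training
#'   individuals (a joint train+test matrix enables [predict_gblup()]).
#' @param D_diag diagonal of the residual weight matrix, one entry per row of
#'   `G_mat` (default all 1).
#' @param reml if `TRUE` (default) estimate the variance components by REML;
#'   otherwise use the supplied `sigma_g_sq`, `sigma_e_sq`.
#' @param train_idx rows of `G_mat` carrying the records in `y` (default all).
#' @param sigma_g_sq,sigma_e_sq variance components used when `reml = FALSE`.
#' @param ridge diagonal ridge added when the eigenvalues fall below zero.
#' @return object of class `gblup_fit` with `mu`, `sigma_g_sq`, `sigma_e_sq`,
#'   `gebv` (training individuals), `loglik`, plus the inputs needed for
#'   prediction.
#' @export
fit_gblup <- function(y, G_mat, D_diag = NULL, reml = TRUE, train_idx = NULL,
                      sigma_g_sq = NULL, sigma_e_sq = NULL, ridge = 1e-6) {
  n_all <- nrow(G_mat)
  D_diag <- D_diag %||% rep(1, n_all)
  if (is.matrix(D_diag)) D_diag <- diag(D_diag)
  if (any(D_diag <= 0)) abort("residual weights d_ii must be positive")
  train_idx <- train_idx %||% seq_len(n_all)
  if (length(y) != length(train_idx)) {
    abort("y must have one record per training individual")
  }
  s <- 1 / sqrt(D_diag[train_idx])
  Gw <- G_mat[train_idx, train_idx, drop = FALSE] * tcrossprod(s)
  eg <- eigen(Gw, symmetric = TRUE)
  lam <- eg$values
  if (min(lam) < 0) lam <- lam + (ridge - min(lam))
  U <- eg$vectors
  ystar <- drop(crossprod(U, s * y))
  xstar <- drop(crossprod(U, s))
  nt <- length(y)

  restricted_ll <- function(log_gamma) {
    gam <- exp(log_gamma)
    w <- gam * lam + 1
    mu <- sum(xstar * ystar / w) / sum(xstar^2 / w)
    rssw <- sum((ystar - xstar * mu)^2 / w)
    se2 <- rssw / (nt - 1)
    -0.5 * ((nt - 1) * log(se2) + sum(log(w)) + log(sum(xstar^2 / w)) +
              (nt - 1))
  }

  if (reml) {
    opt <- optimize(restricted_ll, c(-12, 12), maximum = TRUE, tol = 1e-8)
    gam <- exp(opt$maximum)
    w <- gam * lam + 1
    mu <- sum(xstar * ystar / w) / sum(xstar^2 / w)
    se2 <- sum((ystar - xstar * mu)^2 / w) / (nt - 1)
    sg2 <- gam * se2
    ll <- opt$objective
  } else {
    if (is.null(sigma_g_sq) || is.null(sigma_e_sq)) {
      abort("supply sigma_g_sq and sigma_e_sq when reml = FALSE")
    }
    sg2 <- sigma_g_sq; se2 <- sigma_e_sq
    gam <- sg2 / se2
    w <- gam * lam + 1
    mu <- sum(xstar * ystar / w) / sum(xstar^2 / w)
    ll <- restricted_ll(log(gam))
  }

  # BLUP of the training individuals: sigma_g^2 G V^{-1} (y - 1 mu)
  a <- drop(crossprod(U, s * (y - mu))) / (sg2 * lam + se2)
  gebv <- sg2 * drop(G_mat[train_idx, train_idx, drop = FALSE] %*%
                       (s * drop(U %*% a)))
  structure(
    list(G_mat = G_mat, D_diag = D_diag, train_idx = train_idx, y = y,
         mu = mu, sigma_g_sq = sg2, sigma_e_sq = se2, gebv = gebv,
         loglik = ll, ridge = ridge,
         h2_hat = sg2 / (sg2 + se2)),
    class = "gblup_fit"
  )
}

#' Predict genomic breeding values for validation individuals
#'
#' `g_test = G[test, train] (G[train, train] + lambda D_train)^{-1}
#' (y_train - 1 mu)` with `lambda = sigma_e^2 / sigma_g^2`, the standard
#' relationship-based BLUP extension; requires `G_mat` built jointly on
#' training and test individuals.
#'
#' @param model a `gblup_fit` whose `G_mat` covers the test individuals.
#' @param test_idx rows of `G_mat` to predict.
#' @param train_idx training rows (defaults to those used in the fit).
#' @return numeric vector of predicted breeding values (add `model$mu` for
#'   predicted records).
#' @export
predict_gblup <- function(model, test_idx, train_idx = NULL) {
  stopifnot(inherits(model, "gblup_fit"))
  train_idx <- train_idx %||% model$train_idx
  lambda <- model$sigma_e_sq / model$sigma_g_sq
  M <- model$G_mat[train_idx, train_idx, drop = FALSE] +
    lambda * diag(model$D_diag[train_idx], nrow = length(train_idx))
  rhs <- model$y - model$mu
  sol <- tryCatch(
    solve(M, rhs),
    error = function(e) solve(M + model$ridge * diag(nrow(M)), rhs)
  )
  drop(model$G_mat[test_idx, train_idx, drop = FALSE] %*% sol)
}

#' Gibbs sampler configuration for the Bayesian regressions
#'
#' @param n_iter,burn_in,thin chain length, burn-in and thinning (defaults
#'   50000 / 20000 / 50; tests and the evaluation harness scale these down).
#' @param pi_fixed proportion of no-effect SNPs held fixed in BayesB
#'   (default 0.95) and used as the reference sparsity when deriving the
#'   default prior scale.
#' @param df_v prior degrees of freedom of the effect-variance scaled
#'   inverse chi-square (default 4.2, the field convention).
#' @param scale_S2 prior scale; the default (NULL) solves for the scale that
#'   puts the prior mean genetic variance at `h2_prior` of the phenotypic
#'   variance on standardized data.
#' @param h2_prior assumed heritability behind the default prior scale.
#' @param nu_e,Se2 residual-variance prior degrees of freedom and scale
#'   (`Se2 = NULL` defaults to `var(y) * (1 - h2_prior)`).
#' @param seed integer seed (the chain uses R's RNG).
#' @return object of class `bayes_config`.
#' @export
bayes_config <- function(n_iter = 50000, burn_in = 20000, thin = 50,
                         pi_fixed = 0.95, df_v = 4.2, scale_S2 = NULL,
                         h2_prior = 0.3, nu_e = 4, Se2 = NULL, seed = 1) {
  if (burn_in >= n_iter) abort("burn_in must be smaller than n_iter")
  if (thin < 1) abort("thin must be >= 1")
  structure(
    list(n_iter = n_iter, burn_in = burn_in, thin = thin,
         pi_fixed = pi_fixed, df_v = df_v, scale_S2 = scale_S2,
         h2_prior = h2_prior, nu_e = nu_e, Se2 = Se2, seed = seed),
    class = "bayes_config"
  )
}

bayes_default_scale <- function(cfg, y, J) {
  # prior mean per-SNP effect variance times the expected number of included
  # unit-variance SNPs matches h2_prior of var(y)
  target <- cfg$h2_prior * var(y) / max((1 - cfg$pi_fixed) * J, 1)
  target * (cfg$df_v - 2) / cfg$df_v
}

run_gibbs <- function(X_std, y, cfg, update_pi, common_var, update_mu,
                      update_sigma_e, fix_sigma_beta, sigma_beta_fixed,
                      method) {
  S2 <- cfg$scale_S2 %||% bayes_default_scale(cfg, y, ncol(X_std))
  Se2 <- cfg$Se2 %||% (var(y) * (1 - cfg$h2_prior))
  set.seed(cfg$seed)
  res <- .gibbs_ssvs(
    X_std, y, cfg$n_iter, cfg$burn_in, cfg$thin,
    pi0 = if (update_pi) 0.5 else cfg$pi_fixed,
    update_pi = update_pi, common_var = common_var,
    df_v = cfg$df_v, scale_S2 = S2,
    update_mu = update_mu, update_sigma_e = update_sigma_e,
    sigma_e2_init = var(y), nu_e = cfg$nu_e, Se2 = Se2,
    fix_sigma_beta = fix_sigma_beta, sigma_beta_fixed = sigma_beta_fixed
  )
  structure(
    list(method = method, beta_mean = res$beta_mean, beta_se = res$beta_se,
         incl_freq = res$incl_freq,
         pi_samples = if (update_pi) res$pi_samples else NULL,
         mu_mean = res$mu_mean, sigma_e_mean = res$sigma_e_mean,
         n_samples = res$n_samples, config = cfg),
    class = "bayes_fit"
  )
}

#' Fit BayesB by single-site Gibbs sampling
#'
#' Marker effects have independent per-SNP variances with a scaled inverse
#' chi-square prior (marginally t-distributed effects) and a fixed proportion
#' `pi_fixed` of no-effect SNPs. `beta_mean`/`beta_se` are posterior means
#' and standard deviations of the marker effects over the retained samples.
#'
#' @param X_std standardized genotype matrix.
#' @param y response vector (standardized DRPs).
#' @param cfg a [bayes_config()].
#' @param update_mu,update_sigma_e set `FALSE` to freeze the intercept or
#'   residual variance (exact-posterior comparisons).
#' @param fix_sigma_beta,sigma_beta_fixed freeze the effect variance at a
#'   known value (exact-posterior comparisons).
#' @return object of class `bayes_fit`.
#' @export
fit_bayesb <- function(X_std, y, cfg = bayes_config(), update_mu = TRUE,
                       update_sigma_e = TRUE, fix_sigma_beta = FALSE,
                       sigma_beta_fixed = 0.01) {
  run_gibbs(X_std, y, cfg, update_pi = FALSE, common_var = FALSE,
            update_mu, update_sigma_e, fix_sigma_beta, sigma_beta_fixed,
            method = "bayesb")
}

#' Fit BayesCpi by single-site Gibbs sampling
#'
#' Marker effects share one normal slab variance (scaled inverse chi-square
#' prior) and the no-effect proportion `pi` is unknown with a uniform (0,1)
#' prior, updated each sweep from `Beta(#null + 1, #nonnull + 1)`.
#'
#' @inheritParams fit_bayesb
#' @param update_pi set `FALSE` to hold `pi` at `cfg$pi_fixed`.
#' @return object of class `bayes_fit`; `pi_samples` holds the retained
#'   posterior draws of `pi`.
#' @export
fit_bayescpi <- function(X_std, y, cfg = bayes_config(), update_mu = TRUE,
                         update_sigma_e = TRUE, update_pi = TRUE,
                         fix_sigma_beta = FALSE, sigma_beta_fixed = 0.01) {
  run_gibbs(X_std, y, cfg, update_pi = update_pi, common_var = TRUE,
            update_mu, update_sigma_e, fix_sigma_beta, sigma_beta_fixed,
            method = "bayescpi")
}

#' @export
predict.bayes_fit <- function(object, X_new_std, ...) {
  drop(X_new_std %*% object$beta_mean) + object$mu_mean
}

#' Random-forest configuration
#'
#' @param grid_trees candidate forest sizes.
#' @param grid_depth candidate maximum depths (0 = unlimited).
#' @param inner_folds folds of the inner cross-validation used for the grid
#'   search (default 5).
#' @param seed integer seed.
#' @return object of class `rf_config`.
#' @export
rf_config <- function(grid_trees = c(100, 300, 500), grid_depth = c(5, 10, 0),
                      inner_folds = 5, seed = 1) {
  if (any(grid_trees < 1)) abort("all tree counts must be >= 1")
  structure(
    list(grid_trees = grid_trees, grid_depth = grid_depth,
         inner_folds = inner_folds, seed = seed),
    class = "rf_config"
  )
}

#' Fit a random-forest regression with inner-CV grid search
#'
#' Hyperparameters (number of trees, maximum depth) are chosen by mean
#' squared error over an inner k-fold cross-validation run entirely on the
#' training data; the final forest is refit on the full training data with
#' the best pair.
#'
#' @param X predictor matrix (dosages; standardization is immaterial for
#'   trees).
#' @param y response vector.
#' @param cfg an [rf_config()].
#' @return object of class `rf_fit` with the fitted `ranger` forest, the
#'   chosen hyperparameters (`best`) and the full CV `grid`.
#' @export
fit_rf <- function(X, y, cfg = rf_config()) {
  if (inherits(X, "genotype_matrix")) X <- X$dosages
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- nrow(X)
  set.seed(cfg$seed)
  fold <- sample(rep(seq_len(cfg$inner_folds), length.out = n))
  grid <- tidyr::expand_grid(trees = cfg$grid_trees, depth = cfg$grid_depth)
  grid$cv_mse <- map_dbl(seq_len(nrow(grid)), function(i) {
    errs <- map_dbl(seq_len(cfg$inner_folds), function(f) {
      tr <- fold != f
      rf <- ranger::ranger(
        x = X[tr, , drop = FALSE], y = y[tr],
        num.trees = grid$trees[i], max.depth = grid$depth[i],
        seed = cfg$seed, num.threads = 1
      )
      pv <- predict(rf, data = X[!tr, , drop = FALSE],
                    num.threads = 1)$predictions
      mean((y[!tr] - pv)^2)
    })
    mean(errs)
  })
  best <- grid[which.min(grid$cv_mse), ]
  model <- ranger::ranger(
    x = X, y = y, num.trees = best$trees, max.depth = best$depth,
    seed = cfg$seed, num.threads = 1
  )
  structure(list(model = model, best = best, grid = grid, config = cfg),
            class = "rf_fit")
}

#' @export
predict.rf_fit <- function(object, X_new, ...) {
  if (inherits(X_new, "genotype_matrix")) X_new <- X_new$dosages
  if (is.null(colnames(X_new))) {
    colnames(X_new) <- paste0("x", seq_len(ncol(X_new)))
  }
  predict(object$model, data = X_new, num.threads = 1)$predictions
}
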