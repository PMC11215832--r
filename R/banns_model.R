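# Two-layer sparse Bayesian neural network over SNP-sets: a K-component
# spike-and-slab mixture regression on SNPs feeds leaky-ReLU neurons (one per
# SNP-set) whose weights carry a single-slab spike-and-slab prior. Both
# layers are fitted by mean-field variational EM with a grid over the
# log-inclusion probability; grid points are combined by ELBO importance
# weights.

#' Variational EM configuration
#'
#' @param K number of slab mixture components in the SNP layer (default 3:
#'   large, moderate and small effects).
#' @param sigma0_sq initial effect-variance scale; the K slab variances start
#'   at `sigma0_sq * 10^seq(-1, 1, length.out = K)` and are re-estimated by
#'   EM from the first sweep on, floored at `sigma0_sq / 10` to prevent
#'   slab collapse.
#' @param L number of grid points for the inclusion-probability
#'   hyperparameter; the grid is uniform in `log(pi)` on `[-log(J), 0]`
#'   (respectively `[-log(G), 0]` for the set layer) and grid points are
#'   averaged with ELBO importance weights.
#' @param elbo_tol convergence tolerance on successive evidence lower bounds.
#' @param max_iter iteration cap per grid point.
#' @param seed integer seed for the random initialization.
#' @param init `"prior"` draws initial weights from the prior (default);
#'   `"zero"` is a deterministic all-spike start for regression tests.
#' @return an object of class `vem_config`.
#' @export
vem_config <- function(K = 3, sigma0_sq = 0.01, L = 20, elbo_tol = 1e-4,
                       max_iter = 10000, seed = 1,
                       init = c("prior", "zero")) {
  if (K < 1) abort("K must be >= 1")
  if (elbo_tol <= 0) abort("elbo_tol must be positive")
  if (max_iter < 1) abort("max_iter must be >= 1")
  structure(
    list(K = K, sigma0_sq = sigma0_sq, L = L, elbo_tol = elbo_tol,
         max_iter = max_iter, seed = seed, init = match.arg(init)),
    class = "vem_config"
  )
}

#' Leaky rectified linear unit
#'
#' Identity for positive inputs, `slope * x` otherwise.
#'
#' @param x numeric vector or matrix.
#' @param slope negative-side slope (default 0.01).
#' @return same shape as `x`.
#' @examples
#' leaky_relu(c(2, -1, 0))  # 2, -0.01, 0
#' @export
leaky_relu <- function(x, slope = 0.01) {
  pmax(x, 0) + slope * pmin(x, 0)
}

#' Mean-center and unit-scale genotypes and trait
#'
#' Columns of `X` and the vector `y` are centered and scaled to unit variance
#' (n - 1 divisor). The constants are returned so new data can be mapped onto
#' the training scale and predictions mapped back.
#'
#' @param X numeric matrix (or [genotype_matrix()]).
#' @param y optional trait vector.
#' @return list with `X`, `y` and `constants` (`x_center`, `x_scale`,
#'   `y_center`, `y_scale`).
#' @export
standardize_xy <- function(X, y = NULL) {
  if (inherits(X, "genotype_matrix")) X <- X$dosages
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  zero <- which(scl < 1e-12)
  if (length(zero) > 0) {
    nm <- colnames(X)[zero] %||% as.character(zero)
    abort(paste("zero-variance column(s):", paste(head(nm, 5), collapse = ", ")))
  }
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  out <- list(X = Xs, constants = list(x_center = ctr, x_scale = scl))
  if (!is.null(y)) {
    if (sd(y) < 1e-12) abort("trait vector is constant")
    out$constants$y_center <- mean(y)
    out$constants$y_scale <- sd(y)
    out$y <- (y - out$constants$y_center) / out$constants$y_scale
  }
  out
}

vb_pi_grid <- function(p, L) {
  unique(exp(seq(-log(p), 0, length.out = max(L, 1))))
}

# Run the variational coordinate ascent over an inclusion-probability grid
# with warm starts, then combine grid points by ELBO importance weights.
vb_grid_fit <- function(X, y, cfg, K, pi_grid = NULL, sigma2_init = NULL,
                        tau2_init = NULL, update_sigma = TRUE,
                        update_eta = TRUE, update_tau = TRUE) {
  n <- nrow(X); J <- ncol(X)
  if (J < 1) abort("need at least one predictor")
  pi_grid <- pi_grid %||% vb_pi_grid(J, cfg$L)
  pi_grid <- sort(pi_grid)
  sigma2 <- sigma2_init %||%
    (cfg$sigma0_sq * if (K > 1) 10^seq(-1, 1, length.out = K) else 1)
  eta <- rep(1 / K, K)
  tau2 <- tau2_init %||% var(y)
  set.seed(cfg$seed)
  mu <- if (cfg$init == "prior") {
    matrix(rnorm(J * K, sd = sqrt(rep(sigma2, each = J))), J, K)
  } else {
    matrix(0, J, K)
  }
  alpha <- matrix(pi_grid[1] * eta, J, K, byrow = TRUE)

  use_xtx <- J <= 2000 && J <= 2 * n
  XtX <- if (use_xtx) crossprod(X) else NULL

  fits <- vector("list", length(pi_grid))
  for (l in seq_along(pi_grid)) {
    fit <- .vb_mix_fit(X, y, sigma2, eta, pi_grid[l], tau2, alpha, mu,
                       cfg$elbo_tol, cfg$max_iter, update_sigma, update_eta,
                       update_tau, cfg$sigma0_sq / 10, XtX)
    fits[[l]] <- fit
    # warm start the next (larger-pi) grid point
    alpha <- fit$alpha; mu <- fit$mu
    sigma2 <- fit$sigma2; eta <- fit$eta; tau2 <- fit$tau2
  }

  elbo_final <- map_dbl(fits, ~ .x$elbo[length(.x$elbo)])
  w <- exp(elbo_final - max(elbo_final))
  w <- w / sum(w)

  wsum <- function(get) Reduce(`+`, map2(fits, w, ~ get(.x) * .y))
  alpha_bar <- wsum(function(f) f$alpha)
  am <- wsum(function(f) f$alpha * f$mu)
  am2 <- wsum(function(f) f$alpha * (f$mu^2 + f$s2))
  mu_bar <- ifelse(alpha_bar > 1e-12, am / pmax(alpha_bar, 1e-12), 0)
  s2_bar <- pmax(ifelse(alpha_bar > 1e-12,
                        am2 / pmax(alpha_bar, 1e-12) - mu_bar^2, 0), 0)
  eta_bar <- drop(wsum(function(f) matrix(f$eta, 1)))
  eta_bar <- eta_bar / sum(eta_bar)

  list(
    alpha = alpha_bar, mu = mu_bar, s2 = s2_bar,
    beta = rowSums(am), pip = pmin(rowSums(alpha_bar), 1),
    pi = sum(w * pi_grid), eta = eta_bar,
    sigma2 = drop(wsum(function(f) matrix(f$sigma2, 1))),
    tau2 = sum(w * map_dbl(fits, "tau2")),
    grid = tibble(
      pi = pi_grid, elbo = elbo_final, weight = w,
      converged = map_dbl(fits, "converged") > 0,
      n_iter = map_int(fits, "n_iter")
    ),
    elbo_traces = map(fits, "elbo"),
    converged = all(map_dbl(fits, "converged") > 0)
  )
}

#' Fit the SNP layer
#'
#' Mean-field variational approximation to the K-component spike-and-slab
#' mixture regression of the standardized trait on standardized SNP dosages.
#' The inclusion probability is handled by an `L`-point grid on `log(pi)`
#' over `[-log(J), 0]` (a uniform prior on `log(pi)`), each point fitted by
#' coordinate ascent with closed-form EM updates of the mixture proportions,
#' slab variances and residual variance; grid points are averaged with ELBO
#' importance weights.
#'
#' @param X_std standardized genotype matrix.
#' @param y_std standardized trait vector.
#' @param cfg a [vem_config()].
#' @param pi_grid optional explicit grid of inclusion probabilities
#'   (overrides the default); mainly for calibration tests.
#' @param sigma2_init,tau2_init optional starting variances.
#' @param update_sigma,update_eta,update_tau set to `FALSE` to hold the
#'   corresponding hyperparameter fixed (used when comparing against exact
#'   posteriors).
#' @return object of class `snp_layer_posterior`: per-SNP responsibilities
#'   `alpha` (J x K), conditional means `mu` and variances `s2`, marginal
#'   means `beta_theta`, `pip`, mixture summaries `pi_theta`, `eta_theta`,
#'   `sigma_theta_sq`, residual variance `tau_theta_sq`, the hyperparameter
#'   `grid` and per-grid-point `elbo_traces`.
#' @export
fit_snp_layer <- function(X_std, y_std, cfg = vem_config(), pi_grid = NULL,
                          sigma2_init = NULL, tau2_init = NULL,
                          update_sigma = TRUE, update_eta = TRUE,
                          update_tau = TRUE) {
  res <- vb_grid_fit(X_std, y_std, cfg, cfg$K, pi_grid, sigma2_init,
                     tau2_init, update_sigma, update_eta, update_tau)
  structure(
    list(alpha = res$alpha, mu = res$mu, s2 = res$s2,
         pi_theta = res$pi, eta_theta = res$eta,
         sigma_theta_sq = res$sigma2, tau_theta_sq = res$tau2,
         beta_theta = res$beta, pip = res$pip, grid = res$grid,
         elbo_traces = res$elbo_traces, converged = res$converged),
    class = "snp_layer_posterior"
  )
}

#' Fit the SNP-set layer
#'
#' Single-slab spike-and-slab variational regression of the standardized
#' trait on the standardized hidden neurons, with the inclusion probability
#' on an `L`-point grid over `[-log(G), 0]`. The inclusion probabilities
#' `gamma` are the SNP-set posterior inclusion probabilities.
#'
#' @inheritParams fit_snp_layer
#' @param H_std standardized hidden-neuron matrix from
#'   [build_hidden_inputs()].
#' @return object of class `set_layer_posterior` with `gamma`, `mu_w`,
#'   `s2_w`, `pi_w`, `sigma_w_sq`, `tau_w_sq`, `beta_w`, `grid`,
#'   `elbo_traces`.
#' @export
fit_set_layer <- function(H_std, y_std, cfg = vem_config(), pi_grid = NULL,
                          sigma2_init = NULL, tau2_init = NULL,
                          update_sigma = TRUE, update_tau = TRUE) {
  res <- vb_grid_fit(H_std, y_std, cfg, K = 1, pi_grid, sigma2_init,
                     tau2_init, update_sigma, update_eta = FALSE,
                     update_tau = update_tau)
  structure(
    list(gamma = drop(res$alpha), mu_w = drop(res$mu), s2_w = drop(res$s2),
         pi_w = res$pi, sigma_w_sq = res$sigma2[1], tau_w_sq = res$tau2,
         beta_w = res$beta, pip = res$pip, grid = res$grid,
         elbo_traces = res$elbo_traces, converged = res$converged),
    class = "set_layer_posterior"
  )
}

#' Build the hidden-neuron matrix
#'
#' Column g is `leaky_relu(X_g %*% beta_theta[g-members] + b1[g])`: the
#' deterministic nonlinear neuron of SNP-set g given the SNP-layer marginal
#' posterior means.
#'
#' @param beta_theta SNP-layer marginal posterior means (or a
#'   `snp_layer_posterior`).
#' @param X_std standardized genotype matrix used for the SNP layer.
#' @param partition a [snp_set_partition()].
#' @param b1 per-set bias vector (default zero: centered inputs absorb it).
#' @param slope leaky-ReLU negative-side slope.
#' @return n x G matrix of raw (uncentered) neurons.
#' @export
build_hidden_inputs <- function(beta_theta, X_std, partition,
                                b1 = NULL, slope = 0.01) {
  if (inherits(beta_theta, "snp_layer_posterior")) {
    beta_theta <- beta_theta$beta_theta
  }
  G <- partition$G
  b1 <- b1 %||% numeric(G)
  if (length(beta_theta) != ncol(X_std)) {
    abort("beta_theta length does not match the genotype columns")
  }
  H <- matrix(0, nrow(X_std), G)
  for (g in seq_len(G)) {
    idx <- partition$sets$snp_indices[[g]]
    H[, g] <- leaky_relu(
      drop(X_std[, idx, drop = FALSE] %*% beta_theta[idx]) + b1[g], slope
    )
  }
  colnames(H) <- partition$sets$set_id
  H
}

#' Fit the two-layer SNP-set network
#'
#' Orchestrates standardization, the SNP layer, construction and
#' standardization of the hidden neurons, and the SNP-set layer. Hidden
#' columns with zero variance (sets whose SNP-layer means are exactly zero)
#' are dropped from the set layer with a warning and get weight zero. Biases
#' are absorbed by centering: `b1 = 0` and `b2 = 0` on the standardized
#' scale, the de-standardization constants playing the intercept role.
#'
#' @param X genotype dosages (matrix or [genotype_matrix()]).
#' @param y trait vector (e.g. de-regressed proofs).
#' @param partition a [snp_set_partition()] over the columns of `X`.
#' @param cfg a [vem_config()].
#' @return object of class `bann_fit`.
#' @export
fit_banns <- function(X, y, partition, cfg = vem_config()) {
  if (inherits(X, "genotype_matrix")) X <- X$dosages
  if (ncol(X) != partition$n_snps) {
    abort("partition does not match the genotype matrix")
  }
  std <- standardize_xy(X, y)
  snp <- fit_snp_layer(std$X, std$y, cfg)
  H <- build_hidden_inputs(snp$beta_theta, std$X, partition)
  h_center <- colMeans(H)
  h_scale <- apply(H, 2, sd)
  keep <- which(h_scale > 1e-12)
  if (length(keep) == 0) {
    abort("all hidden neurons are constant: the SNP layer selected nothing")
  }
  if (length(keep) < partition$G) {
    warn(sprintf("%d zero-variance hidden neuron(s) dropped from the set layer",
                 partition$G - length(keep)))
  }
  H_std <- sweep(sweep(H[, keep, drop = FALSE], 2, h_center[keep]),
                 2, h_scale[keep], "/")
  set_cfg <- cfg
  set_cfg$seed <- cfg$seed + 1L
  setl <- fit_set_layer(H_std, std$y, set_cfg)
  fitted <- drop(H_std %*% setl$beta_w)
  structure(
    list(
      snp_layer = snp, set_layer = setl, partition = partition,
      kept_sets = keep, b1 = numeric(partition$G), b2 = 0,
      activation_slope = 0.01,
      constants = c(std$constants,
                    list(h_center = h_center, h_scale = h_scale)),
      fitted = fitted, snp_linear_predictor = drop(std$X %*% snp$beta_theta),
      elbo_trace = list(snp = snp$elbo_traces, set = setl$elbo_traces),
      converged = snp$converged && setl$converged,
      config = cfg, n = nrow(std$X)
    ),
    class = "bann_fit"
  )
}

#' @export
print.bann_fit <- function(x, ...) {
  cat(sprintf(
    "<bann_fit> n = %d, J = %d SNPs, G = %d sets (%d active neurons)\n",
    x$n, length(x$snp_layer$beta_theta), x$partition$G, length(x$kept_sets)
  ))
  cat(sprintf("  converged: %s; pi_theta = %.4f, pi_w = %.4f\n",
              x$converged, x$snp_layer$pi_theta, x$set_layer$pi_w))
  invisible(x)
}

#' Predict from a fitted SNP-set network
#'
#' New genotypes are mapped onto the training standardization, pushed through
#' the hidden neurons with the training SNP-layer means, standardized with
#' the training neuron constants and combined with the set-layer marginal
#' means. Predictions are returned on the standardized-trait scale (the
#' scale all evaluation metrics use).
#'
#' @param object a `bann_fit`.
#' @param X_new genotype dosages with the same variants, in the same order,
#'   as the training data.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.bann_fit <- function(object, X_new, ...) {
  if (inherits(X_new, "genotype_matrix")) X_new <- X_new$dosages
  cst <- object$constants
  if (ncol(X_new) != length(cst$x_center)) {
    abort("X_new does not match the training variants")
  }
  Xs <- sweep(sweep(X_new, 2, cst$x_center), 2, cst$x_scale, "/")
  H <- build_hidden_inputs(object$snp_layer$beta_theta, Xs,
                           object$partition, object$b1,
                           object$activation_slope)
  keep <- object$kept_sets
  H_std <- sweep(sweep(H[, keep, drop = FALSE], 2, cst$h_center[keep]),
                 2, cst$h_scale[keep], "/")
  drop(H_std %*% object$set_layer$beta_w) + object$b2
}

#' Posterior inclusion probabilities of SNPs and SNP-sets
#'
#' The SNP-level PIP is the total slab responsibility `sum_k alpha_jk`; the
#' set-level PIP is the set-layer inclusion probability `gamma_g` (zero for
#' neurons dropped as constant).
#'
#' @param fit a `bann_fit`.
#' @return tibble with columns `layer` (`"snp"` or `"set"`), `id` and `pip`.
#' @export
posterior_inclusion_probabilities <- function(fit) {
  stopifnot(inherits(fit, "bann_fit"))
  pip_set <- numeric(fit$partition$G)
  pip_set[fit$kept_sets] <- fit$set_layer$gamma
  snp_ids <- names(fit$constants$x_center) %||%
    paste0("snp_", seq_along(fit$snp_layer$pip))
  bind_rows(
    tibble(layer = "snp", id = snp_ids, pip = fit$snp_layer$pip),
    tibble(layer = "set", id = fit$partition$sets$set_id, pip = pip_set)
  )
}

#' Phenotypic variance explained at SNP and SNP-set level
#'
#' `pve_snp = V[X beta_theta] / (V[X beta_theta] + tau2_theta)` uses the
#' SNP-layer linear predictor and residual variance (additive effects only);
#' `pve_set = V[H beta_w] / (V[H beta_w] + tau2_w)` uses the set-layer
#' predictor through the activation, so non-additive within-set effects
#' contribute. V is the sample variance.
#'
#' @param fit a `bann_fit`.
#' @param X_std optional standardized genotype matrix to evaluate on
#'   (defaults to the training predictors stored in the fit).
#' @return list with `pve_snp` and `pve_set`, both in `[0, 1]`.
#' @export
estimate_pve <- function(fit, X_std = NULL) {
  stopifnot(inherits(fit, "bann_fit"))
  if (is.null(X_std)) {
    lp_snp <- fit$snp_linear_predictor
    lp_set <- fit$fitted
  } else {
    lp_snp <- drop(X_std %*% fit$snp_layer$beta_theta)
    H <- build_hidden_inputs(fit$snp_layer$beta_theta, X_std, fit$partition,
                             fit$b1, fit$activation_slope)
    keep <- fit$kept_sets
    H_std <- sweep(sweep(H[, keep, drop = FALSE], 2,
                         fit$constants$h_center[keep]),
                   2, fit$constants$h_scale[keep], "/")
    lp_set <- drop(H_std %*% fit$set_layer$beta_w)
  }
  clamp <- function(x) min(max(x, 0), 1)
  vs <- var(lp_snp); vw <- var(lp_set)
  list(
    pve_snp = if (vs > 0) clamp(vs / (vs + fit$snp_layer$tau_theta_sq)) else 0,
    pve_set = if (vw > 0) clamp(vw / (vw + fit$set_layer$tau_w_sq)) else 0
  )
}
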