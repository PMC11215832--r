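# broom-style tidiers for the fitted objects.

#' @export
tidy.bann_fit <- function(x, ...) {
  pip <- posterior_inclusion_probabilities(x)
  est <- c(x$snp_layer$beta_theta,
           {
             bw <- numeric(x$partition$G)
             bw[x$kept_sets] <- x$set_layer$beta_w
             bw
           })
  mutate(pip, estimate = est) |>
    select("layer", term = "id", "estimate", "pip")
}

#' @export
glance.bann_fit <- function(x, ...) {
  pve <- estimate_pve(x)
  tibble(
    n = x$n, n_snps = length(x$snp_layer$beta_theta), n_sets = x$partition$G,
    n_active_sets = length(x$kept_sets), converged = x$converged,
    pi_theta = x$snp_layer$pi_theta, pi_w = x$set_layer$pi_w,
    tau2_theta = x$snp_layer$tau_theta_sq, tau2_w = x$set_layer$tau_w_sq,
    pve_snp = pve$pve_snp, pve_set = pve$pve_set
  )
}

#' @export
tidy.gblup_fit <- function(x, ...) {
  tibble(
    term = c("mu", "sigma_g_sq", "sigma_e_sq"),
    estimate = c(x$mu, x$sigma_g_sq, x$sigma_e_sq)
  )
}

#' @export
glance.gblup_fit <- function(x, ...) {
  tibble(
    n = length(x$y), sigma_g_sq = x$sigma_g_sq, sigma_e_sq = x$sigma_e_sq,
    h2_hat = x$h2_hat, loglik = x$loglik
  )
}

#' @export
tidy.bayes_fit <- function(x, ...) {
  tibble(
    term = names(x$beta_mean) %||% paste0("snp_", seq_along(x$beta_mean)),
    estimate = x$beta_mean, std.error = x$beta_se,
    incl_freq = x$incl_freq
  )
}

#' @export
glance.bayes_fit <- function(x, ...) {
  tibble(
    method = x$method, mu = x$mu_mean, sigma_e_sq = x$sigma_e_mean,
    pi_mean = if (is.null(x$pi_samples)) x$config$pi_fixed
              else mean(x$pi_samples),
    mean_beta_se = mean(x$beta_se), n_samples = x$n_samples
  )
}

#' @export
tidy.snp_set_partition <- function(x, ...) {
  mutate(x$sets, set_size = lengths(.data$snp_indices)) |>
    select("set_id", "label", "kind", "set_size", "snp_indices")
}
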