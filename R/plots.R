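# ggplot2 displays for experiments, fits and partitions.

#' @export
autoplot.banngp_experiment <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$replicate_metrics,
    cols = c("accuracy", "dispersion", "mse"),
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$method, y = .data$value,
                                     fill = .data$method)) +
    ggplot2::stat_summary(fun = mean, geom = "col") +
    ggplot2::stat_summary(fun.data = ggplot2::mean_se, geom = "errorbar",
                          width = 0.25) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none",
                   axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Posterior inclusion probabilities along the panel
#'
#' Point plot of SNP- and SNP-set-level PIPs, faceted by layer.
#'
#' @param fit a `bann_fit`.
#' @return a ggplot object.
#' @export
plot_pip <- function(fit) {
  pip <- posterior_inclusion_probabilities(fit) |>
    group_by(.data$layer) |>
    mutate(index = row_number()) |>
    ungroup()
  ggplot2::ggplot(pip, ggplot2::aes(x = .data$index, y = .data$pip)) +
    ggplot2::geom_point(size = 0.7, alpha = 0.7) +
    ggplot2::facet_wrap(~layer, scales = "free_x") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "index along panel", y = "posterior inclusion probability") +
    ggplot2::theme_minimal()
}

#' Distribution of SNP-set sizes
#'
#' Bar chart of the number of SNPs per SNP-set, coloured by set kind.
#'
#' @param partition a [snp_set_partition()].
#' @return a ggplot object.
#' @export
plot_partition_sizes <- function(partition) {
  ggplot2::ggplot(partition_summary(partition),
                  ggplot2::aes(x = .data$set_size, y = .data$n_sets,
                               fill = .data$kind)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "SNPs per set", y = "number of sets") +
    ggplot2::theme_minimal()
}

#' Evidence lower bound traces of a network fit
#'
#' One line per hyperparameter grid point, faceted by layer; within each
#' coordinate-ascent run the trace is non-decreasing.
#'
#' @param fit a `bann_fit`.
#' @return a ggplot object.
#' @export
plot_elbo_trace <- function(fit) {
  tr <- imap(fit$elbo_trace, function(traces, layer) {
    imap(traces, function(e, l) {
      tibble(layer = layer, grid_point = l, iteration = seq_along(e),
             elbo = e)
    }) |> list_rbind()
  }) |> list_rbind()
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$iteration, y = .data$elbo,
                                   group = .data$grid_point)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::facet_wrap(~layer, scales = "free") +
    ggplot2::labs(x = "iteration", y = "evidence lower bound") +
    ggplot2::theme_minimal()
}
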