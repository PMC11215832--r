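# Replicated cross-validation harness, prediction metrics and method
# comparison. Every method consumes the identical fold plan and identical
# standardized DRPs; fold plans are hashed so the fairness contract is
# checkable.

#' Standardize de-regressed proofs
#'
#' Mean 0, variance 1 (n - 1 divisor). When `center`/`scale` are supplied
#' (training-fold constants), they are applied instead of being recomputed,
#' the leak-free protocol for validation animals.
#'
#' @param drp numeric vector.
#' @param center,scale optional pre-computed constants.
#' @return standardized vector with attributes `center` and `scale`.
#' @export
standardize_drp <- function(drp, center = NULL, scale = NULL) {
  if (is.null(center)) {
    if (sd(drp) < 1e-12) abort("DRP vector is constant")
    center <- mean(drp); scale <- sd(drp)
  }
  out <- (drp - center) / scale
  attr(out, "center") <- center
  attr(out, "scale") <- scale
  out
}

#' Build a replicated k-fold cross-validation plan
#'
#' Each replicate draws a fresh random partition of the individuals into k
#' folds whose sizes differ by at most one; within a replicate the test sets
#' partition all individuals.
#'
#' @param n number of individuals.
#' @param k folds per replicate (default 5).
#' @param reps replicates (default 5).
#' @param seed integer seed.
#' @return tibble with columns `replicate`, `fold`, `train_idx`, `test_idx`
#'   (list columns of integer vectors).
#' @export
make_cv_folds <- function(n, k = 5, reps = 5, seed = 1) {
  if (n < k) abort("need at least k individuals")
  set.seed(seed)
  plans <- map(seq_len(reps), function(r) {
    f <- sample(rep(seq_len(k), length.out = n))
    tibble(
      replicate = r, fold = seq_len(k),
      train_idx = map(seq_len(k), ~ which(f != .x)),
      test_idx = map(seq_len(k), ~ which(f == .x))
    )
  })
  bind_rows(plans)
}

#' Prediction accuracy
#'
#' Pearson correlation between standardized DRPs and predicted values in the
#' validation set, divided by the mean DRP accuracy `r_bar` (mean square root
#' of the DRP reliabilities of the validation animals).
#'
#' @param sdrp_test standardized DRPs of the validation animals.
#' @param pv_test predicted values.
#' @param r_bar mean square-root reliability of the validation DRPs.
#' @return scalar accuracy.
#' @export
accuracy <- function(sdrp_test, pv_test, r_bar) {
  if (length(sdrp_test) != length(pv_test) || length(sdrp_test) < 3) {
    abort("need matching vectors of length >= 3")
  }
  if (r_bar <= 0) abort("r_bar must be positive")
  if (sd(pv_test) < 1e-12) abort("predicted values have zero variance")
  cor(sdrp_test, pv_test) / r_bar
}

#' Dispersion of predictions
#'
#' Ordinary least-squares slope of the regression of standardized DRPs on
#' predicted values; 1 means neither over- nor under-dispersion, below 1
#' over-dispersed (inflated) predictions.
#'
#' @inheritParams accuracy
#' @return scalar slope.
#' @export
dispersion <- function(sdrp_test, pv_test) {
  if (sd(pv_test) < 1e-12) abort("predicted values have zero variance")
  cov(sdrp_test, pv_test) / var(pv_test)
}

#' Mean squared error between standardized DRPs and predictions
#'
#' @inheritParams accuracy
#' @return scalar MSE (>= 0).
#' @export
mse <- function(sdrp_test, pv_test) {
  if (length(sdrp_test) != length(pv_test)) abort("length mismatch")
  mean((sdrp_test - pv_test)^2)
}

#' Compare methods by paired t-tests on replicate means
#'
#' Fold-level accuracies are averaged to replicate means; for every method
#' pair within a trait a paired two-sided t-test (df = replicates - 1) is run
#' on the replicate means and p-values are Bonferroni-adjusted by the number
#' of pairs within the trait.
#'
#' @param results tibble with columns `method`, `trait`, `replicate` and
#'   `accuracy` (fold- or replicate-level).
#' @param metric column to compare (default `"accuracy"`).
#' @return tibble with one row per trait and method pair: `mean_diff`,
#'   `statistic`, `df`, `p_value`, `p_adj`.
#' @export
compare_methods <- function(results, metric = "accuracy") {
  rep_means <- results |>
    group_by(.data$method, .data$trait, .data$replicate) |>
    summarise(value = mean(.data[[metric]]), .groups = "drop")
  counts <- rep_means |>
    group_by(.data$method, .data$trait) |>
    summarise(n = n(), .groups = "drop")
  if (length(unique(counts$n)) != 1) {
    abort("every method needs the same number of replicates per trait")
  }
  out <- list()
  for (tr in unique(rep_means$trait)) {
    sub <- filter(rep_means, .data$trait == tr)
    methods <- sort(unique(sub$method))
    if (length(methods) < 2) next
    pairs <- utils::combn(methods, 2, simplify = FALSE)
    rows <- map(pairs, function(pr) {
      x <- sub$value[sub$method == pr[1]][order(sub$replicate[sub$method == pr[1]])]
      y <- sub$value[sub$method == pr[2]][order(sub$replicate[sub$method == pr[2]])]
      d <- x - y
      if (sd(d) < 1e-15) {
        if (all(abs(d) < 1e-15)) {
          p <- 1; tstat <- 0
        } else {
          warn("zero within-pair variance with non-zero difference: p -> 0")
          p <- 0; tstat <- sign(mean(d)) * Inf
        }
      } else {
        tstat <- mean(d) / (sd(d) / sqrt(length(d)))
        p <- 2 * pt(abs(tstat), df = length(d) - 1, lower.tail = FALSE)
      }
      tibble(trait = tr, method_a = pr[1], method_b = pr[2],
             mean_diff = mean(d), statistic = tstat, df = length(d) - 1,
             p_value = p)
    })
    rows <- bind_rows(rows)
    rows$p_adj <- pmin(rows$p_value * length(pairs), 1)
    out[[tr]] <- rows
  }
  bind_rows(out)
}

#' Configure a full synthetic prediction experiment
#'
#' @param n,J individuals and SNPs of the simulated panel.
#' @param maf_range,ld_rho,chrom_count genotype simulation knobs (see
#'   [simulate_genotypes()]).
#' @param gene_density,gene_len_bp gene-map knobs (see [simulate_gene_map()]).
#' @param arch a [sim_architecture()] describing the trait.
#' @param rel_range DRP reliability range (see [simulate_drp()]).
#' @param methods subset of `"bann_gene"`, `"bann_100kb"`, `"gblup"`,
#'   `"bayesb"`, `"bayescpi"`, `"rf"`.
#' @param cv_k,cv_reps cross-validation folds and replicates (default 5 x 5).
#' @param window_bp window width for the window partition.
#' @param truth_partition partition used to anchor the simulated enrichment
#'   (`"window"` or `"gene"`).
#' @param vem,bayes,rf method configurations.
#' @param qc_maf_min,qc_hwe_alpha marker QC thresholds.
#' @param trait_name label used in the results tables.
#' @param seed master seed; all stage seeds derive from it.
#' @return object of class `experiment_config`.
#' @export
experiment_config <- function(n = 2000, J = 1000, maf_range = c(0.05, 0.5),
                              ld_rho = 0.2, chrom_count = 5,
                              gene_density = 5, gene_len_bp = c(2000, 50000),
                              arch = sim_architecture(),
                              rel_range = c(0.5, 0.9),
                              methods = c("bann_100kb", "gblup"),
                              cv_k = 5, cv_reps = 5, window_bp = 100000,
                              truth_partition = c("window", "gene"),
                              vem = vem_config(), bayes = bayes_config(),
                              rf = rf_config(), qc_maf_min = 0.01,
                              qc_hwe_alpha = 1e-6, trait_name = "sim_trait",
                              seed = 1) {
  known <- c("bann_gene", "bann_100kb", "gblup", "bayesb", "bayescpi", "rf")
  if (!all(methods %in% known)) {
    abort(paste("unknown method; choose from:", paste(known, collapse = ", ")))
  }
  structure(
    list(n = n, J = J, maf_range = maf_range, ld_rho = ld_rho,
         chrom_count = chrom_count, gene_density = gene_density,
         gene_len_bp = gene_len_bp, arch = arch, rel_range = rel_range,
         methods = methods, cv_k = cv_k, cv_reps = cv_reps,
         window_bp = window_bp,
         truth_partition = match.arg(truth_partition), vem = vem,
         bayes = bayes, rf = rf, qc_maf_min = qc_maf_min,
         qc_hwe_alpha = qc_hwe_alpha, trait_name = trait_name, seed = seed),
    class = "experiment_config"
  )
}

#' Run a full synthetic genomic-prediction experiment
#'
#' Simulates a genotype panel, gene map, trait architecture and de-regressed
#' proofs, then evaluates the requested methods under one shared replicated
#' cross-validation plan: identical folds, identical training-fold DRP
#' standardization, identical validation reliabilities. Fold-level accuracy,
#' dispersion and MSE are recorded per method, replicate and fold;
#' variance-explained summaries are collected for the network fits.
#'
#' @param config an [experiment_config()].
#' @return object of class `banngp_experiment`: list with `metrics`
#'   (fold-level tibble), `replicate_metrics`, `summary` (per-method means),
#'   `comparisons` (paired t-table), `pve`, `pip_summary`, `truth`,
#'   `fold_hash` and `manifest`.
#' @export
run_experiment <- function(config = experiment_config()) {
  stopifnot(inherits(config, "experiment_config"))
  seed <- config$seed
  g <- simulate_genotypes(config$n, config$J, config$maf_range[1],
                          config$maf_range[2], config$ld_rho,
                          config$chrom_count, seed = seed)
  qc <- apply_qc(g, config$qc_maf_min, config$qc_hwe_alpha)
  g <- qc$genotypes
  gene_map <- simulate_gene_map(g$variants, config$gene_density,
                                config$gene_len_bp, seed = seed + 1L)
  part_window <- partition_by_window(g$variants, config$window_bp)
  part_gene <- partition_by_gene(g$variants, gene_map)
  truth_part <- if (config$truth_partition == "window") part_window else part_gene

  arch <- config$arch
  arch$seed <- seed + 2L
  sim <- simulate_phenotypes(g, truth_part, arch)
  traits <- simulate_drp(sim$truth, sim$phenotype, config$rel_range,
                         h2 = arch$h2_target, seed = seed + 3L)
  folds <- make_cv_folds(nrow(g$dosages), config$cv_k, config$cv_reps,
                         seed = seed + 4L)
  fold_hash <- hash(folds[, c("replicate", "fold", "test_idx")])

  X <- g$dosages
  grm <- if ("gblup" %in% config$methods) build_grm(X) else NULL
  d_diag <- (1 - traits$r2_drp) / traits$r2_drp

  metrics <- list()
  pve_rows <- list()
  pip_rows <- list()
  for (i in seq_len(nrow(folds))) {
    rep_i <- folds$replicate[i]; fold_i <- folds$fold[i]
    tr <- folds$train_idx[[i]]; te <- folds$test_idx[[i]]
    sdrp_tr <- standardize_drp(traits$drp[tr])
    sdrp_te <- standardize_drp(traits$drp[te], attr(sdrp_tr, "center"),
                               attr(sdrp_tr, "scale"))
    r_bar <- mean(sqrt(traits$r2_drp[te]))
    fit_seed <- seed + 100L * rep_i + 10L * fold_i

    for (m in config$methods) {
      pv <- switch(
        m,
        bann_gene = ,
        bann_100kb = {
          part <- if (m == "bann_gene") part_gene else part_window
          vem <- config$vem; vem$seed <- fit_seed
          fit <- fit_banns(X[tr, , drop = FALSE], sdrp_tr, part, vem)
          pve <- estimate_pve(fit)
          pve_rows[[length(pve_rows) + 1L]] <- tibble(
            method = m, replicate = rep_i, fold = fold_i,
            pve_snp = pve$pve_snp, pve_set = pve$pve_set
          )
          pip <- posterior_inclusion_probabilities(fit)
          pip_rows[[length(pip_rows) + 1L]] <- pip |>
            group_by(.data$layer) |>
            summarise(mean_pip = mean(.data$pip), max_pip = max(.data$pip),
                      min_pip = min(.data$pip), .groups = "drop") |>
            mutate(method = m, replicate = rep_i, fold = fold_i)
          predict(fit, X[te, , drop = FALSE])
        },
        gblup = {
          fit <- fit_gblup(sdrp_tr, grm, d_diag, train_idx = tr)
          fit$mu + predict_gblup(fit, te)
        },
        bayesb = ,
        bayescpi = {
          std <- standardize_xy(X[tr, , drop = FALSE])
          Xte <- sweep(sweep(X[te, , drop = FALSE], 2,
                             std$constants$x_center),
                       2, std$constants$x_scale, "/")
          bcfg <- config$bayes; bcfg$seed <- fit_seed
          fit <- if (m == "bayesb") fit_bayesb(std$X, sdrp_tr, bcfg)
                 else fit_bayescpi(std$X, sdrp_tr, bcfg)
          predict(fit, Xte)
        },
        rf = {
          rcfg <- config$rf; rcfg$seed <- fit_seed
          fit <- fit_rf(X[tr, , drop = FALSE], sdrp_tr, rcfg)
          predict(fit, X[te, , drop = FALSE])
        }
      )
      metrics[[length(metrics) + 1L]] <- tibble(
        method = m, trait = config$trait_name, replicate = rep_i,
        fold = fold_i, accuracy = accuracy(sdrp_te, pv, r_bar),
        dispersion = dispersion(sdrp_te, pv), mse = mse(sdrp_te, pv),
        r_bar = r_bar
      )
    }
  }
  metrics <- bind_rows(metrics)
  replicate_metrics <- metrics |>
    group_by(.data$method, .data$trait, .data$replicate) |>
    summarise(accuracy = mean(.data$accuracy),
              dispersion = mean(.data$dispersion), mse = mean(.data$mse),
              .groups = "drop")
  summary_tab <- replicate_metrics |>
    group_by(.data$method, .data$trait) |>
    summarise(accuracy = mean(.data$accuracy),
              dispersion = mean(.data$dispersion), mse = mean(.data$mse),
              .groups = "drop")
  comparisons <- if (length(config$methods) > 1) {
    compare_methods(metrics)
  } else {
    tibble()
  }
  structure(
    list(
      metrics = metrics, replicate_metrics = replicate_metrics,
      summary = summary_tab, comparisons = comparisons,
      pve = bind_rows(pve_rows), pip_summary = bind_rows(pip_rows),
      truth = sim$truth, traits = traits, fold_hash = fold_hash,
      config = config,
      manifest = list(
        config_hash = hash(config), seed = seed, fold_hash = fold_hash,
        n = config$n, J_post_qc = ncol(X),
        G_window = part_window$G, G_gene = part_gene$G
      )
    ),
    class = "banngp_experiment"
  )
}

#' @export
print.banngp_experiment <- function(x, ...) {
  cat("<banngp_experiment>\n")
  print(x$summary)
  invisible(x)
}

#' Write an experiment bundle to disk
#'
#' Tidy TSVs (fold-level metrics, comparisons, variance explained) plus a
#' JSON manifest capturing the configuration hash and seeds.
#'
#' @param bundle a `banngp_experiment`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(bundle, dir) {
  stopifnot(inherits(bundle, "banngp_experiment"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(x, f) {
    write.table(as.data.frame(x), file.path(dir, f), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  tsv(bundle$metrics, "metrics.tsv")
  if (nrow(bundle$comparisons) > 0) tsv(bundle$comparisons, "comparisons.tsv")
  if (nrow(bundle$pve) > 0) tsv(bundle$pve, "pve.tsv")
  if (nrow(bundle$pip_summary) > 0) tsv(bundle$pip_summary, "pip_summary.tsv")
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
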