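# Synthetic dairy-cattle style data: genotype panels with controllable MAF
# and LD, gene maps, sparse mixed-effect trait architectures with within-set
# epistasis, and de-regressed proofs with heterogeneous reliabilities.

#' Simulate a biallelic SNP panel
#'
#' Dosages are sums of two haplotypes. Within a chromosome, haplotype alleles
#' follow a first-order autoregressive latent-Gaussian process with parameter
#' `ld_rho`, giving adjacent-marker linkage disequilibrium that decays
#' geometrically with marker distance; chromosomes are independent. Marker
#' positions are uniform on each chromosome. This is a controllable-knob LD
#' model, not a coalescent simulation.
#'
#' @param n number of individuals.
#' @param J number of SNPs (split near-evenly across chromosomes).
#' @param maf_low,maf_high allele-frequency range, `0 < maf_low <= maf_high
#'   <= 0.5`; per-SNP frequencies are uniform on the range.
#' @param ld_rho adjacent-haplotype latent correlation in `[0, 1)`.
#' @param chrom_count number of chromosomes.
#' @param seed integer seed; identical seeds give identical panels.
#' @param chrom_len_bp chromosome length in bp (default: 50 kb per SNP on the
#'   chromosome, the approximate marker spacing of a 50k bovine array).
#' @return a [genotype_matrix()].
#' @export
simulate_genotypes <- function(n, J, maf_low = 0.05, maf_high = 0.5,
                               ld_rho = 0, chrom_count = 1, seed = 1,
                               chrom_len_bp = NULL) {
  if (n < 1 || J < 1) abort("n and J must be positive")
  if (!(maf_low > 0 && maf_low <= maf_high && maf_high <= 0.5)) {
    abort("need 0 < maf_low <= maf_high <= 0.5")
  }
  if (ld_rho < 0 || ld_rho >= 1) abort("ld_rho must be in [0, 1)")
  set.seed(seed)
  sizes <- diff(round(seq(0, J, length.out = chrom_count + 1)))
  dos <- vector("list", chrom_count)
  maps <- vector("list", chrom_count)
  idx0 <- 0L
  for (cc in seq_len(chrom_count)) {
    Jc <- sizes[cc]
    if (Jc == 0L) next
    len <- chrom_len_bp %||% (Jc * 50000)
    if (len < Jc) abort("chromosome too short for the requested SNP count")
    maf <- runif(Jc, maf_low, maf_high)
    pos <- sort(sample.int(len, Jc))
    thr <- qnorm(maf)
    z <- matrix(rnorm(2L * n * Jc), nrow = 2L * n, ncol = Jc)
    if (ld_rho > 0 && Jc > 1) {
      sc <- sqrt(1 - ld_rho^2)
      for (j in 2:Jc) z[, j] <- ld_rho * z[, j - 1] + sc * z[, j]
    }
    alleles <- sweep(z, 2, thr, "<") * 1L
    dos[[cc]] <- alleles[seq_len(n), , drop = FALSE] +
      alleles[n + seq_len(n), , drop = FALSE]
    maps[[cc]] <- tibble(
      variant_id = sprintf("snp%06d", idx0 + seq_len(Jc)),
      chrom = as.character(cc), pos_bp = pos,
      allele_a = "A", allele_b = "B"
    )
    idx0 <- idx0 + Jc
  }
  genotype_matrix(do.call(cbind, dos), bind_rows(maps),
                  paste0("ind_", seq_len(n)), sort = FALSE)
}

#' Simulate a non-overlapping gene map over a variant panel
#'
#' Places non-overlapping gene intervals uniformly along each chromosome
#' spanned by the variants, leaving inter-gene gaps so some SNPs fall in
#' intergenic territory.
#'
#' @param variants variant map tibble (e.g. `g$variants`).
#' @param gene_density genes per Mb; 0 gives an empty annotation.
#' @param gene_len_bp length range `c(min, max)` in bp.
#' @param seed integer seed.
#' @return gene annotation tibble (`gene_id`, `chrom`, `start_bp`, `end_bp`,
#'   `strand`).
#' @export
simulate_gene_map <- function(variants, gene_density = 5,
                              gene_len_bp = c(2000, 50000), seed = 1) {
  if (nrow(variants) == 0) abort("variant map is empty")
  if (gene_density < 0) abort("gene_density must be non-negative")
  set.seed(seed)
  out <- list()
  for (cc in unique(variants$chrom)) {
    span <- max(variants$pos_bp[variants$chrom == cc])
    ng <- round(gene_density * span / 1e6)
    if (ng == 0) next
    len <- round(runif(ng, gene_len_bp[1], gene_len_bp[2]))
    gap <- span - sum(len)
    if (gap < 0) {
      abort("gene density and length are infeasible for the chromosome span")
    }
    offsets <- sort(runif(ng, 0, gap))
    starts <- floor(offsets) + cumsum(c(0, len[-ng])) + 1
    out[[cc]] <- tibble(
      gene_id = sprintf("gene_%s_%03d", cc, seq_len(ng)),
      chrom = cc, start_bp = as.integer(starts),
      end_bp = as.integer(starts + len - 1), strand = "+"
    )
  }
  if (length(out) == 0) {
    return(tibble(gene_id = character(), chrom = character(),
                  start_bp = integer(), end_bp = integer(),
                  strand = character()))
  }
  bind_rows(out)
}

#' Describe a simulated trait architecture
#'
#' @param pi_causal proportion of SNPs with a non-zero additive effect. With
#'   `n_enriched_sets` set, causal SNPs are instead confined to that many
#'   randomly chosen SNP-sets (every SNP inside an enriched set is causal),
#'   mirroring set-level enrichment.
#' @param mixture_props proportions of large/moderate/small effect classes
#'   among causal SNPs (sums to 1).
#' @param mixture_vars variances of the three effect classes (relative scale
#'   only; the residual is calibrated to `h2_target` afterwards).
#' @param epistasis_frac fraction of SNP-sets holding at least two causal
#'   SNPs that receive one pairwise product-term interaction.
#' @param h2_target broad-sense heritability of the simulated phenotype.
#' @param n_enriched_sets optional count of enriched SNP-sets (see
#'   `pi_causal`).
#' @param epi_effect_sd standard deviation of interaction effects; the
#'   default gives each interaction roughly four times the variance of a
#'   typical causal SNP so the non-additive signal is material.
#' @param seed integer seed.
#' @return an object of class `sim_architecture`.
#' @export
sim_architecture <- function(pi_causal = 0.05,
                             mixture_props = c(0.1, 0.2, 0.7),
                             mixture_vars = c(0.1, 0.01, 0.001),
                             epistasis_frac = 0, h2_target = 0.33,
                             n_enriched_sets = NULL, epi_effect_sd = NULL,
                             seed = 1) {
  if (abs(sum(mixture_props) - 1) > 1e-8) abort("mixture_props must sum to 1")
  if (any(mixture_vars <= 0)) abort("mixture_vars must be positive")
  if (pi_causal < 0 || pi_causal > 1) abort("pi_causal must be in [0, 1]")
  if (h2_target <= 0 || h2_target >= 1) abort("h2_target must be in (0, 1)")
  if (epistasis_frac < 0 || epistasis_frac > 1) {
    abort("epistasis_frac must be in [0, 1]")
  }
  structure(
    list(
      pi_causal = pi_causal, mixture_props = mixture_props,
      mixture_vars = mixture_vars, epistasis_frac = epistasis_frac,
      h2_target = h2_target, n_enriched_sets = n_enriched_sets,
      epi_effect_sd = epi_effect_sd %||%
        2 * sqrt(sum(mixture_props * mixture_vars)),
      seed = seed
    ),
    class = "sim_architecture"
  )
}

#' Simulate phenotypes from a sparse mixed-effect architecture
#'
#' Additive effects are drawn from a three-component normal mixture (large /
#' moderate / small effects) for causal SNPs and are zero elsewhere; effects
#' act on column-standardized dosages. For a fraction of SNP-sets containing
#' at least two causal SNPs, one pairwise product-term interaction between
#' two causal members is added, yielding within-set non-additive variance.
#' Residual noise is rescaled so the realized sample heritability
#' `var(tbv) / var(phenotype)` matches `h2_target` exactly.
#'
#' @param g a [genotype_matrix()] (complete, post-QC).
#' @param partition a [snp_set_partition()] covering all SNPs of `g`.
#' @param arch a [sim_architecture()].
#' @return list with `phenotype` (numeric n-vector) and `truth`, an object of
#'   class `sim_truth` holding `beta_true`, `interaction_terms` (tibble:
#'   `set_id`, `snp_j`, `snp_k`, `effect`), `tbv` and `realized_h2`.
#' @export
simulate_phenotypes <- function(g, partition, arch) {
  stopifnot(inherits(arch, "sim_architecture"))
  J <- ncol(g$dosages); n <- nrow(g$dosages)
  covered <- sort(unlist(partition$sets$snp_indices))
  if (!identical(covered, seq_len(J))) {
    abort("partition must cover every SNP of the genotype matrix")
  }
  set.seed(arch$seed)
  X <- scale(g$dosages)
  if (anyNA(X)) abort("monomorphic SNPs present: run apply_qc() first")

  enriched <- integer(0)
  if (!is.null(arch$n_enriched_sets)) {
    G <- nrow(partition$sets)
    if (arch$n_enriched_sets > G) abort("more enriched sets than sets")
    enriched <- sample.int(G, arch$n_enriched_sets)
    causal <- sort(unlist(partition$sets$snp_indices[enriched]))
  } else {
    causal <- which(runif(J) < arch$pi_causal)
  }
  beta <- numeric(J)
  if (length(causal) > 0) {
    comp <- sample.int(length(arch$mixture_props), length(causal),
                       replace = TRUE, prob = arch$mixture_props)
    beta[causal] <- rnorm(length(causal),
                          sd = sqrt(arch$mixture_vars[comp]))
  }
  tbv <- drop(X %*% beta)

  # within-set product-term epistasis among causal SNPs
  interactions <- tibble(set_id = character(), snp_j = integer(),
                         snp_k = integer(), effect = double())
  if (arch$epistasis_frac > 0) {
    eligible <- which(map_int(partition$sets$snp_indices,
                              ~ sum(.x %in% causal)) >= 2L)
    if (length(enriched) > 0) eligible <- intersect(eligible, enriched)
    n_epi <- round(arch$epistasis_frac * length(eligible))
    if (length(eligible) == 0 || n_epi == 0) {
      warn("no SNP-set holds two causal SNPs: no interaction terms emitted")
    } else {
      chosen <- sample(eligible, n_epi)
      rows <- vector("list", n_epi)
      for (i in seq_along(chosen)) {
        s <- chosen[i]
        pair <- sample(intersect(partition$sets$snp_indices[[s]], causal), 2)
        w <- X[, pair[1]] * X[, pair[2]]
        w <- w - mean(w)
        sw <- sd(w)
        if (sw > 0) w <- w / sw
        eff <- rnorm(1, sd = arch$epi_effect_sd)
        tbv <- tbv + w * eff
        rows[[i]] <- tibble(set_id = partition$sets$set_id[s],
                            snp_j = pair[1], snp_k = pair[2], effect = eff)
      }
      interactions <- bind_rows(rows)
    }
  }

  e <- rnorm(n)
  vg <- var(tbv)
  if (vg > 0) {
    # orthogonalize against the genetic values so the sample covariance is
    # exactly zero, making the realized heritability match h2_target exactly
    e <- e - mean(e)
    tc <- tbv - mean(tbv)
    e <- e - tc * sum(e * tc) / sum(tc^2)
    e <- e / sd(e) * sqrt(vg * (1 - arch$h2_target) / arch$h2_target)
  }
  phenotype <- tbv + e
  truth <- structure(
    list(beta_true = beta, interaction_terms = interactions, tbv = tbv,
         realized_h2 = if (vg > 0) vg / var(phenotype) else 0),
    class = "sim_truth"
  )
  list(phenotype = phenotype, truth = truth)
}

#' Simulate de-regressed proofs with heterogeneous reliabilities
#'
#' Per animal, a DRP reliability is drawn uniformly on `rel_range` and the
#' pseudo-phenotype is the true genetic value plus Gaussian noise with
#' variance `var(tbv) * (1 - REL) / REL`, so the squared correlation between
#' DRP and genetic value is about REL in expectation — the same reliability
#' algebra that drives the diagonal residual weighting in the mixed model.
#'
#' @param truth a `sim_truth` from [simulate_phenotypes()].
#' @param phenotype the matching phenotype vector (kept for interface
#'   symmetry; the noise law is anchored on the genetic variance).
#' @param rel_range reliability range `c(low, high)`, `0 < low <= high < 1`.
#' @param h2 trait heritability recorded on every animal.
#' @param seed integer seed.
#' @return trait tibble (`sample_id`, `drp`, `rel_ebv`, `h2`) completed by
#'   [derive_trait_weights()].
#' @export
simulate_drp <- function(truth, phenotype, rel_range = c(0.5, 0.9), h2,
                         seed = 1) {
  stopifnot(inherits(truth, "sim_truth"))
  if (!(rel_range[1] > 0 && rel_range[1] <= rel_range[2] &&
        rel_range[2] < 1)) {
    abort("need 0 < rel_range[1] <= rel_range[2] < 1")
  }
  set.seed(seed)
  n <- length(truth$tbv)
  rel <- runif(n, rel_range[1], rel_range[2])
  vg <- var(truth$tbv)
  drp <- truth$tbv + rnorm(n, sd = sqrt(vg * (1 - rel) / rel))
  derive_trait_weights(tibble(
    sample_id = paste0("ind_", seq_len(n)),
    drp = drp, rel_ebv = rel, h2 = h2
  ))
}
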