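test_that("simulate_genotypes is deterministic in the seed and validates arguments", {
  g1 <- simulate_genotypes(30, 10, seed = 42)
  g2 <- simulate_genotypes(30, 10, seed = 42)
  g3 <- simulate_genotypes(30, 10, seed = 43)
  expect_identical(g1$dosages, g2$dosages)
  expect_identical(g1$variants, g2$variants)
  expect_false(identical(g1$dosages, g3$dosages))
  expect_error(simulate_genotypes(0, 10), "positive")
  expect_error(simulate_genotypes(10, 10, maf_low = 0), "maf")
  expect_error(simulate_genotypes(10, 10, maf_high = 0.6), "maf")
  expect_error(simulate_genotypes(10, 10, ld_rho = 1), "ld_rho")
})

test_that("simulated panels have valid dosages, sorted maps and split chromosomes", {
  g <- simulate_genotypes(50, 30, chrom_count = 3, seed = 7)
  expect_true(all(g$dosages %in% 0:2))
  expect_equal(dim(g$dosages), c(50L, 30L))
  expect_identical(sort(unique(g$variants$chrom)), c("1", "2", "3"))
  expect_equal(as.vector(table(g$variants$chrom)), c(10L, 10L, 10L))
  for (cc in unique(g$variants$chrom)) {
    expect_false(is.unsorted(g$variants$pos_bp[g$variants$chrom == cc]))
  }
})

test_that("allele frequencies respect the requested MAF range", {
  g <- simulate_genotypes(2000, 50, maf_low = 0.2, maf_high = 0.4, seed = 8)
  freq <- colMeans(g$dosages) / 2
  maf <- pmin(freq, 1 - freq)
  # sampling noise at n = 2000 is about 0.01
  expect_true(all(maf > 0.15 & maf < 0.45))
})

test_that("ld_rho controls adjacent-marker linkage disequilibrium", {
  g0 <- simulate_genotypes(2000, 100, ld_rho = 0, seed = 9)
  g9 <- simulate_genotypes(2000, 100, ld_rho = 0.9, seed = 9)
  adj_cor <- function(g) {
    r <- sapply(seq_len(ncol(g$dosages) - 1),
                function(j) cor(g$dosages[, j], g$dosages[, j + 1]))
    mean(abs(r))
  }
  expect_lt(adj_cor(g0), 0.06)
  expect_gt(adj_cor(g9), 0.3)
})

test_that("simulate_gene_map places non-overlapping genes inside the span", {
  g <- simulate_genotypes(10, 200, chrom_count = 2, seed = 3)
  ann <- simulate_gene_map(g$variants, gene_density = 5, seed = 4)
  expect_true(nrow(ann) > 0)
  expect_false(anyDuplicated(ann$gene_id) > 0)
  for (cc in unique(ann$chrom)) {
    sub <- ann[ann$chrom == cc, ]
    sub <- sub[order(sub$start_bp), ]
    expect_true(all(sub$start_bp <= sub$end_bp))
    expect_true(all(sub$start_bp >= 1))
    if (nrow(sub) > 1) {
      expect_true(all(sub$start_bp[-1] > sub$end_bp[-nrow(sub)]))
    }
    span <- max(g$variants$pos_bp[g$variants$chrom == cc])
    expect_true(all(sub$end_bp <= span + max(sub$end_bp - sub$start_bp)))
  }
  expect_identical(simulate_gene_map(g$variants, gene_density = 4, seed = 5),
                   simulate_gene_map(g$variants, gene_density = 4, seed = 5))
  empty <- simulate_gene_map(g$variants, gene_density = 0)
  expect_equal(nrow(empty), 0L)
})

test_that("sim_architecture validates its fields", {
  expect_s3_class(sim_architecture(), "sim_architecture")
  expect_error(sim_architecture(mixture_props = c(0.5, 0.5, 0.5)), "sum to 1")
  expect_error(sim_architecture(mixture_vars = c(0.1, 0, 0.1)), "positive")
  expect_error(sim_architecture(pi_causal = 1.2), "pi_causal")
  expect_error(sim_architecture(h2_target = 1), "h2_target")
  expect_error(sim_architecture(epistasis_frac = -0.1), "epistasis_frac")
})

test_that("simulate_phenotypes calibrates heritability exactly and keeps sparsity", {
  g <- simulate_genotypes(400, 100, seed = 11)
  part <- partition_by_window(g$variants)
  arch <- sim_architecture(pi_causal = 0.1, h2_target = 0.4, seed = 12)
  sim <- simulate_phenotypes(g, part, arch)
  expect_equal(sim$truth$realized_h2, 0.4, tolerance = 1e-12)
  expect_equal(var(sim$truth$tbv) / var(sim$phenotype), 0.4, tolerance = 1e-12)
  expect_lt(mean(sim$truth$beta_true != 0), 0.25)
  expect_gt(sum(sim$truth$beta_true != 0), 0)
  expect_equal(length(sim$phenotype), 400L)
})

test_that("enriched-set architectures confine causal SNPs to the chosen sets", {
  g <- simulate_genotypes(200, 120, seed = 13)
  part <- partition_by_window(g$variants, window_bp = 500000)
  arch <- sim_architecture(n_enriched_sets = 3, seed = 14)
  sim <- simulate_phenotypes(g, part, arch)
  causal <- which(sim$truth$beta_true != 0)
  sets_hit <- which(purrr::map_lgl(part$sets$snp_indices,
                                   ~ any(.x %in% causal)))
  expect_lte(length(sets_hit), 3L)
  # every SNP of a hit set is causal
  expect_true(all(unlist(part$sets$snp_indices[sets_hit]) %in% causal))
  expect_error(
    simulate_phenotypes(g, part, sim_architecture(n_enriched_sets = 10000)),
    "more enriched sets"
  )
})

test_that("within-set epistasis adds interactions between causal members of one set", {
  g <- simulate_genotypes(300, 100, seed = 15)
  part <- partition_by_window(g$variants, window_bp = 500000)
  arch <- sim_architecture(n_enriched_sets = 4, epistasis_frac = 1, seed = 16)
  sim <- simulate_phenotypes(g, part, arch)
  it <- sim$truth$interaction_terms
  expect_gt(nrow(it), 0)
  for (i in seq_len(nrow(it))) {
    members <- part$sets$snp_indices[[which(part$sets$set_id == it$set_id[i])]]
    expect_true(all(c(it$snp_j[i], it$snp_k[i]) %in% members))
    expect_true(all(sim$truth$beta_true[c(it$snp_j[i], it$snp_k[i])] != 0))
  }
})

test_that("epistasis warns when no set carries two causal SNPs", {
  g <- simulate_genotypes(100, 40, seed = 17)
  part <- partition_by_window(g$variants, window_bp = 40000)  # singleton-ish sets
  arch <- sim_architecture(pi_causal = 0.05, epistasis_frac = 0.5, seed = 18)
  expect_warning(simulate_phenotypes(g, part, arch), "no SNP-set")
})

test_that("simulate_phenotypes rejects partitions that do not cover the panel", {
  g <- simulate_genotypes(50, 20, seed = 19)
  part <- partition_by_window(g$variants[1:10, ])
  expect_error(simulate_phenotypes(g, part, sim_architecture()), "cover")
})

test_that("simulate_drp draws reliabilities in range and anchors noise on them", {
  g <- simulate_genotypes(3000, 60, seed = 20)
  part <- partition_by_window(g$variants)
  sim <- simulate_phenotypes(g, part, sim_architecture(pi_causal = 0.2, seed = 21))
  traits <- simulate_drp(sim$truth, sim$phenotype, rel_range = c(0.6, 0.8),
                         h2 = 0.33, seed = 22)
  expect_equal(nrow(traits), 3000L)
  expect_true(all(traits$rel_ebv >= 0.6 & traits$rel_ebv <= 0.8))
  expect_equal(traits$r2_drp, traits$rel_ebv, tolerance = 1e-12)
  # squared DRP-genetic-value correlation tracks the mean reliability
  r2 <- cor(traits$drp, sim$truth$tbv)^2
  expect_gt(r2, 0.55)
  expect_lt(r2, 0.85)
  expect_identical(
    simulate_drp(sim$truth, sim$phenotype, h2 = 0.33, seed = 5)$drp,
    simulate_drp(sim$truth, sim$phenotype, h2 = 0.33, seed = 5)$drp
  )
  expect_error(simulate_drp(sim$truth, sim$phenotype, rel_range = c(0.5, 1),
                            h2 = 0.33), "rel_range")
})
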