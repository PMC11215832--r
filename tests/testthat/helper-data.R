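# Small builders shared across test files.

toy_variants <- function(pos, chrom = "1") {
  tibble::tibble(
    variant_id = sprintf("v%03d", seq_along(pos)),
    chrom = rep_len(chrom, length(pos)), pos_bp = pos,
    allele_a = "A", allele_b = "B"
  )
}

toy_genotypes <- function(n = 20, J = 5, seed = 1) {
  set.seed(seed)
  dos <- matrix(sample(0:2, n * J, replace = TRUE), n, J)
  genotype_matrix(dos, toy_variants(seq_len(J) * 1000))
}

# standardized design and trait with one strong predictor
toy_signal <- function(n = 500, J = 20, j_causal = 3, seed = 1) {
  set.seed(seed)
  X <- scale(matrix(rnorm(n * J), n, J))
  y <- drop(scale(X[, j_causal] + rnorm(n, sd = sd(X[, j_causal]))))
  list(X = X, y = y)
}
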