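# SNP-set partitioning: gene-annotation based sets (with intergenic pooling)
# and fixed physical windows. Each set becomes one hidden-layer neuron.

#' Construct a SNP-set partition
#'
#' @param sets tibble with columns `set_id`, `label`, `kind` (one of
#'   `"gene"`, `"intergenic"`, `"window"`) and `snp_indices` (list column of
#'   integer vectors).
#' @param n_snps total number of SNPs the partition must cover exactly once.
#' @return an object of class `snp_set_partition` with elements `sets`
#'   (tibble) and `G` (set count).
#' @export
snp_set_partition <- function(sets, n_snps) {
  sets <- as_tibble(sets)
  idx <- unlist(sets$snp_indices)
  if (any(lengths(sets$snp_indices) == 0)) abort("every SNP-set must be non-empty")
  if (anyDuplicated(idx)) abort("SNP-sets must be disjoint")
  if (!identical(sort(idx), seq_len(n_snps))) {
    abort("SNP-sets must cover every SNP exactly once")
  }
  if (anyDuplicated(sets$set_id)) abort("set_id values must be unique")
  structure(list(sets = sets, G = nrow(sets), n_snps = n_snps),
            class = "snp_set_partition")
}

#' @export
print.snp_set_partition <- function(x, ...) {
  kinds <- table(x$sets$kind)
  cat(sprintf(
    "<snp_set_partition> %d SNPs in %d sets (%s)\n", x$n_snps, x$G,
    paste(sprintf("%s: %d", names(kinds), kinds), collapse = ", ")
  ))
  invisible(x)
}

check_sorted_variants <- function(variants) {
  ord <- order(variants$chrom, variants$pos_bp)
  if (!identical(ord, seq_len(nrow(variants)))) {
    abort("variants must be sorted by (chrom, pos_bp)")
  }
}

#' Partition SNPs into fixed genomic windows
#'
#' Windows tile each chromosome from coordinate 1, so the SNP at position p
#' falls into window `floor((p - 1) / window_bp)`; positions 1 and
#' `window_bp` share a window while `window_bp + 1` starts the next. Empty
#' windows are not emitted.
#'
#' @param variants variant map tibble sorted by `(chrom, pos_bp)`.
#' @param window_bp window width in bp (default 100 kb).
#' @return a [snp_set_partition()] with all sets of kind `"window"`.
#' @export
partition_by_window <- function(variants, window_bp = 100000) {
  if (window_bp < 1) abort("window_bp must be >= 1")
  check_sorted_variants(variants)
  win <- floor((variants$pos_bp - 1) / window_bp)
  key <- paste0(variants$chrom, ":w", win)
  sets <- tibble(
    set_id = key, snp_index = seq_len(nrow(variants)),
    chrom = variants$chrom, win = win
  ) |>
    group_by(.data$set_id) |>
    summarise(
      snp_indices = list(.data$snp_index),
      chrom = .data$chrom[1], win = .data$win[1], .groups = "drop"
    ) |>
    arrange(.data$chrom, .data$win)
  snp_set_partition(
    tibble(set_id = sets$set_id, label = sets$set_id, kind = "window",
           snp_indices = sets$snp_indices),
    nrow(variants)
  )
}

#' Partition SNPs by gene annotation
#'
#' A SNP inside a gene interval (1-based inclusive, no boundary extension)
#' joins that gene's set. A SNP covered by several overlapping genes goes to
#' the gene whose midpoint is nearest, ties broken by the lexicographically
#' smaller `gene_id`. SNPs inside no gene are pooled per inter-gene interval:
#' all unannotated SNPs lying between the same two genes on a chromosome form
#' one intergenic set, and a chromosome absent from the annotation becomes a
#' single whole-chromosome intergenic set.
#'
#' @param variants variant map tibble sorted by `(chrom, pos_bp)`.
#' @param annotation gene annotation tibble (`gene_id`, `chrom`, `start_bp`,
#'   `end_bp`); may be empty.
#' @return a [snp_set_partition()] with sets of kind `"gene"` and
#'   `"intergenic"`.
#' @export
partition_by_gene <- function(variants, annotation) {
  check_sorted_variants(variants)
  J <- nrow(variants)
  assign_id <- character(J)
  assign_kind <- character(J)
  for (cc in unique(variants$chrom)) {
    vsel <- which(variants$chrom == cc)
    pos <- variants$pos_bp[vsel]
    genes <- annotation[annotation$chrom == cc, , drop = FALSE]
    genes <- genes[order(genes$start_bp, genes$gene_id), , drop = FALSE]
    ng <- nrow(genes)
    if (ng == 0) {
      assign_id[vsel] <- paste0(cc, ":intergenic_0")
      assign_kind[vsel] <- "intergenic"
      next
    }
    nonoverlap <- ng == 1 ||
      all(genes$start_bp[-1] > genes$end_bp[-ng])
    mid <- (genes$start_bp + genes$end_bp) / 2
    for (i in seq_along(vsel)) {
      p <- pos[i]
      if (nonoverlap) {
        k <- findInterval(p, genes$start_bp)
        hit <- if (k > 0 && p <= genes$end_bp[k]) k else integer(0)
      } else {
        hit <- which(genes$start_bp <= p & genes$end_bp >= p)
        if (length(hit) > 1) {
          d <- abs(mid[hit] - p)
          hit <- hit[d == min(d)]
          if (length(hit) > 1) hit <- hit[order(genes$gene_id[hit])][1]
        }
      }
      if (length(hit) == 1) {
        assign_id[vsel[i]] <- genes$gene_id[hit]
        assign_kind[vsel[i]] <- "gene"
      } else {
        k <- sum(genes$end_bp < p)  # inter-gene interval index
        assign_id[vsel[i]] <- paste0(cc, ":intergenic_", k)
        assign_kind[vsel[i]] <- "intergenic"
      }
    }
  }
  sets <- tibble(
    set_id = assign_id, kind = assign_kind, snp_index = seq_len(J),
    chrom = variants$chrom, pos = variants$pos_bp
  ) |>
    group_by(.data$set_id) |>
    summarise(
      kind = .data$kind[1], snp_indices = list(.data$snp_index),
      chrom = .data$chrom[1], pos = min(.data$pos), .groups = "drop"
    ) |>
    arrange(.data$chrom, .data$pos)
  snp_set_partition(
    tibble(set_id = sets$set_id, label = sets$set_id, kind = sets$kind,
           snp_indices = sets$snp_indices),
    J
  )
}

#' Summarise a SNP-set partition
#'
#' @param partition a [snp_set_partition()].
#' @return tibble with one row per (set size, kind) combination and columns
#'   `set_size`, `kind`, `n_sets`; `sum(n_sets)` equals `G`.
#' @export
partition_summary <- function(partition) {
  stopifnot(inherits(partition, "snp_set_partition"))
  tibble(
    set_size = lengths(partition$sets$snp_indices),
    kind = partition$sets$kind
  ) |>
    group_by(.data$set_size, .data$kind) |>
    summarise(n_sets = n(), .groups = "drop") |>
    arrange(.data$set_size, .data$kind)
}
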