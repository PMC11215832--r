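# Genotype, annotation and trait-table input/output plus marker QC.

#' Construct a genotype matrix object
#'
#' Bundles an n x J allele-dosage matrix with its variant map and sample
#' identifiers. Dosages count copies of `allele_b` and must lie in
#' \{0, 1, 2\}; missing values (`NA`) are tolerated only upstream of
#' [apply_qc()].
#'
#' @param dosages numeric matrix, individuals in rows, variants in columns.
#' @param variants tibble with columns `variant_id`, `chrom`, `pos_bp`,
#'   `allele_a`, `allele_b`; one row per column of `dosages`.
#' @param sample_ids character vector, one per row of `dosages`.
#' @param sort if `TRUE` (default), variants (and dosage columns) are ordered
#'   by `(chrom, pos_bp)`.
#' @return an object of class `genotype_matrix`: a list with elements
#'   `dosages`, `variants` and `sample_ids`.
#' @export
genotype_matrix <- function(dosages, variants, sample_ids = NULL, sort = TRUE) {
  dosages <- as.matrix(dosages)
  variants <- as_tibble(variants)
  if (is.null(sample_ids)) {
    sample_ids <- rownames(dosages) %||% paste0("ind_", seq_len(nrow(dosages)))
  }
  n <- nrow(dosages); J <- ncol(dosages)
  if (n < 1L || J < 1L) abort("need at least one individual and one variant")
  if (length(sample_ids) != n) {
    abort("genotype payload does not match the number of sample ids")
  }
  need <- c("variant_id", "chrom", "pos_bp", "allele_a", "allele_b")
  if (!all(need %in% names(variants))) {
    abort(paste("variant map must have columns:", paste(need, collapse = ", ")))
  }
  if (nrow(variants) != J) {
    abort("genotype payload does not match the number of variants")
  }
  if (any(variants$pos_bp < 1)) abort("variant positions must be >= 1")
  if (anyDuplicated(variants[, c("chrom", "pos_bp")])) {
    abort("duplicated (chrom, pos_bp) in variant map")
  }
  bad <- !(dosages %in% c(0, 1, 2)) & !is.na(dosages)
  if (any(bad)) abort("dosages must be allele counts in {0, 1, 2} or NA")
  if (sort) {
    ord <- order(variants$chrom, variants$pos_bp)
    variants <- variants[ord, ]
    dosages <- dosages[, ord, drop = FALSE]
  }
  dimnames(dosages) <- list(sample_ids, variants$variant_id)
  structure(
    list(dosages = dosages, variants = variants, sample_ids = sample_ids),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "<genotype_matrix> %d individuals x %d variants on %d chromosome(s)\n",
    nrow(x$dosages), ncol(x$dosages), length(unique(x$variants$chrom))
  ))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read genotypes from disk
#'
#' Supports a plain allele-dosage table (`dosage-csv`: first column
#' `sample_id`, remaining columns one variant each) and the binary PLINK
#' triplet (`plink-bed`, v1 SNP-major layout with its `.bim`/`.fam`
#' companions). For dosage tables a sidecar variant map
#' (`<path>.variants.csv` with columns `variant_id`, `chrom`, `pos_bp`,
#' `allele_a`, `allele_b`) is read when present; otherwise a single-chromosome
#' map with unit-spaced positions is synthesised.
#'
#' @param path file path; for `plink-bed` either the `.bed` file or the
#'   common prefix of the triplet.
#' @param format `"dosage-csv"` or `"plink-bed"`.
#' @param variant_map optional tibble or CSV path overriding the variant map
#'   (dosage-csv only).
#' @param on_missing `"error"` rejects missing genotypes (default);
#'   `"mean"` fills them with the per-variant mean dosage rounded to the
#'   nearest allele count.
#' @return a [genotype_matrix()] with variants ordered by `(chrom, pos_bp)`.
#' @export
read_genotypes <- function(path, format = c("dosage-csv", "plink-bed"),
                           variant_map = NULL,
                           on_missing = c("error", "mean")) {
  format <- match.arg(format)
  on_missing <- match.arg(on_missing)
  if (format == "dosage-csv") {
    tab <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (names(tab)[1] != "sample_id") {
      abort("dosage table must start with a 'sample_id' column")
    }
    sample_ids <- as.character(tab$sample_id)
    dos <- as.matrix(tab[, -1, drop = FALSE])
    storage.mode(dos) <- "double"
    ids <- colnames(dos)
    if (is.null(variant_map) && file.exists(paste0(path, ".variants.csv"))) {
      variant_map <- paste0(path, ".variants.csv")
    }
    if (is.character(variant_map)) {
      variant_map <- read.csv(variant_map, stringsAsFactors = FALSE)
    }
    if (is.null(variant_map)) {
      variant_map <- tibble(
        variant_id = ids, chrom = "1", pos_bp = seq_along(ids),
        allele_a = "A", allele_b = "B"
      )
    }
    variant_map <- as_tibble(variant_map)
    variant_map$chrom <- as.character(variant_map$chrom)
    variant_map$variant_id <- as.character(variant_map$variant_id)
    if (!setequal(variant_map$variant_id, ids) ||
        nrow(variant_map) != length(ids)) {
      abort("variant map does not match the dosage table columns")
    }
    variant_map <- variant_map[match(ids, variant_map$variant_id), ]
    g <- genotype_matrix(dos, variant_map, sample_ids)
  } else {
    g <- read_plink_bed(path)
  }
  if (anyNA(g$dosages)) {
    if (on_missing == "error") {
      abort(paste(
        "missing genotypes found; re-read with on_missing = \"mean\"",
        "to fill them with per-variant mean dosages"
      ))
    }
    g$dosages <- apply(g$dosages, 2, function(col) {
      col[is.na(col)] <- round(mean(col, na.rm = TRUE))
      col
    })
    dimnames(g$dosages) <- list(g$sample_ids, g$variants$variant_id)
  }
  g
}

#' Write genotypes to disk
#'
#' Inverse of [read_genotypes()]; `dosage-csv` also writes the
#' `<path>.variants.csv` sidecar so a round trip preserves the variant map.
#'
#' @param g a [genotype_matrix()].
#' @param path output path (for `plink-bed`, the prefix of the triplet).
#' @param format `"dosage-csv"` or `"plink-bed"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path, format = c("dosage-csv", "plink-bed")) {
  format <- match.arg(format)
  if (format == "dosage-csv") {
    tab <- data.frame(sample_id = g$sample_ids, g$dosages,
                      check.names = FALSE)
    write.csv(tab, path, row.names = FALSE)
    write.csv(as.data.frame(g$variants), paste0(path, ".variants.csv"),
              row.names = FALSE)
  } else {
    write_plink_bed(g, path)
  }
  invisible(path)
}

# PLINK v1 binary layout: 3 magic bytes (0x6c 0x1b 0x01 = SNP-major), then
# ceiling(n/4) bytes per variant; 2-bit codes 00 = hom allele_a,
# 10 = het, 11 = hom allele_b, 01 = missing (dosage counts allele_b).
plink_byte_table <- function() {
  codes <- c(`0` = 0, `1` = NA_real_, `2` = 1, `3` = 2)
  t(vapply(0:255, function(b) {
    codes[as.character(c(
      bitwAnd(b, 3L), bitwAnd(bitwShiftR(b, 2L), 3L),
      bitwAnd(bitwShiftR(b, 4L), 3L), bitwAnd(bitwShiftR(b, 6L), 3L)
    ))]
  }, numeric(4)))
}

read_plink_bed <- function(prefix) {
  prefix <- sub("\\.bed$", "", prefix)
  bed <- paste0(prefix, ".bed"); bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam)) {
    if (!file.exists(f)) abort(paste("missing PLINK file:", f))
  }
  bimtab <- read.table(bim, stringsAsFactors = FALSE)
  famtab <- read.table(fam, stringsAsFactors = FALSE)
  n <- nrow(famtab); J <- nrow(bimtab)
  raw <- readBin(bed, "raw", n = file.size(bed))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b)) {
    abort("not a PLINK .bed file (bad magic bytes)")
  }
  if (raw[3] != as.raw(0x01)) abort("only SNP-major .bed files are supported")
  bpv <- ceiling(n / 4)
  if (length(raw) - 3L != bpv * J) {
    abort("bed payload size does not match .bim/.fam dimensions")
  }
  lut <- plink_byte_table()
  payload <- matrix(as.integer(raw[-(1:3)]) + 1L, nrow = bpv, ncol = J)
  dos <- matrix(NA_real_, nrow = n, ncol = J)
  for (j in seq_len(J)) {
    vals <- as.vector(t(lut[payload[, j], , drop = FALSE]))
    dos[, j] <- vals[seq_len(n)]
  }
  variants <- tibble(
    variant_id = as.character(bimtab[[2]]), chrom = as.character(bimtab[[1]]),
    pos_bp = as.integer(bimtab[[4]]),
    allele_a = as.character(bimtab[[5]]), allele_b = as.character(bimtab[[6]])
  )
  genotype_matrix(dos, variants, as.character(famtab[[2]]))
}

write_plink_bed <- function(g, prefix) {
  prefix <- sub("\\.bed$", "", prefix)
  n <- nrow(g$dosages); J <- ncol(g$dosages)
  code <- matrix(1L, nrow = n, ncol = J)           # 01 = missing
  code[!is.na(g$dosages) & g$dosages == 0] <- 0L   # hom allele_a
  code[!is.na(g$dosages) & g$dosages == 1] <- 2L   # het
  code[!is.na(g$dosages) & g$dosages == 2] <- 3L   # hom allele_b
  bpv <- ceiling(n / 4)
  padded <- rbind(code, matrix(0L, nrow = bpv * 4 - n, ncol = J))
  shift <- c(1L, 4L, 16L, 64L)
  bytes <- vapply(seq_len(bpv), function(b) {
    rows <- (b - 1L) * 4L + 1:4
    colSums(padded[rows, , drop = FALSE] * shift)
  }, numeric(J))
  bytes <- if (is.matrix(bytes)) t(bytes) else matrix(bytes, nrow = bpv)
  writeBin(c(as.raw(c(0x6c, 0x1b, 0x01)), as.raw(as.vector(bytes))),
           paste0(prefix, ".bed"))
  write.table(
    data.frame(g$variants$chrom, g$variants$variant_id, 0,
               g$variants$pos_bp, g$variants$allele_a, g$variants$allele_b),
    paste0(prefix, ".bim"),
    quote = FALSE, row.names = FALSE, col.names = FALSE, sep = "\t"
  )
  write.table(
    data.frame(g$sample_ids, g$sample_ids, 0, 0, 0, -9),
    paste0(prefix, ".fam"),
    quote = FALSE, row.names = FALSE, col.names = FALSE, sep = "\t"
  )
  invisible(prefix)
}

#' Read gene annotation from a GTF/GFF file
#'
#' Keeps `gene` features only and returns 1-based inclusive intervals, the
#' native GTF convention.
#'
#' @param path a GTF or GFF3 file.
#' @return tibble with columns `gene_id`, `chrom`, `start_bp`, `end_bp`,
#'   `strand`.
#' @export
read_gene_annotation <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("rtracklayer is required to parse GTF/GFF files")
  }
  gr <- rtracklayer::import(path)
  meta <- as.data.frame(gr)
  genes <- meta[!is.na(meta$type) & meta$type == "gene", , drop = FALSE]
  if (nrow(genes) == 0) {
    abort("annotation contains no 'gene' features")
  }
  id <- genes$gene_id %||% genes$ID %||% genes$Name
  if (is.null(id) || all(is.na(id))) id <- paste0("gene_", seq_len(nrow(genes)))
  ann <- tibble(
    gene_id = as.character(id),
    chrom = as.character(genes$seqnames),
    start_bp = as.integer(genes$start),
    end_bp = as.integer(genes$end),
    strand = as.character(genes$strand)
  )
  if (anyDuplicated(ann$gene_id)) abort("gene_id values must be unique")
  arrange(ann, .data$chrom, .data$start_bp)
}

#' Per-variant allele frequencies and Hardy-Weinberg test
#'
#' `snp_stats()` computes the `allele_b` frequency, the minor allele
#' frequency, and a 1-df chi-square goodness-of-fit test of genotype counts
#' against Hardy-Weinberg proportions (an approximation to PLINK's exact
#' test, adequate at the sample sizes simulated here).
#'
#' @param g a [genotype_matrix()] without missing dosages.
#' @return tibble with columns `variant_id`, `freq_b`, `maf`, `hwe_chisq`,
#'   `hwe_p`.
#' @export
snp_stats <- function(g) {
  dos <- g$dosages
  if (anyNA(dos)) abort("missing genotypes: impute or filter before QC")
  n <- nrow(dos)
  n2 <- colSums(dos == 2); n1 <- colSums(dos == 1); n0 <- n - n1 - n2
  p <- (2 * n2 + n1) / (2 * n)
  q <- 1 - p
  exp0 <- n * q^2; exp1 <- 2 * n * p * q; exp2 <- n * p^2
  chisq <- ifelse(
    p == 0 | p == 1, 0,
    (n0 - exp0)^2 / exp0 + (n1 - exp1)^2 / exp1 + (n2 - exp2)^2 / exp2
  )
  tibble(
    variant_id = g$variants$variant_id,
    freq_b = unname(p), maf = unname(pmin(p, q)),
    hwe_chisq = unname(chisq),
    hwe_p = unname(pchisq(chisq, df = 1, lower.tail = FALSE))
  )
}

#' Genotype quality control
#'
#' Removes variants with minor allele frequency below `maf_min` or deviating
#' from Hardy-Weinberg equilibrium at `hwe_alpha` (1-df chi-square test),
#' optionally restricting to a chromosome whitelist first.
#'
#' @param g a [genotype_matrix()] without missing dosages.
#' @param maf_min minimum minor allele frequency retained (default 0.01).
#' @param hwe_alpha Hardy-Weinberg p-value threshold (default 1e-6).
#' @param chrom_keep optional character vector of chromosomes to keep
#'   (default: all chromosomes present).
#' @return list with `genotypes` (filtered [genotype_matrix()]) and `report`
#'   (tibble: one row per input variant with `maf`, `hwe_p`, `removed`,
#'   `reason`).
#' @export
apply_qc <- function(g, maf_min = 0.01, hwe_alpha = 1e-6, chrom_keep = NULL) {
  stats <- snp_stats(g)
  off_chrom <- if (is.null(chrom_keep)) {
    rep(FALSE, nrow(stats))
  } else {
    !(g$variants$chrom %in% chrom_keep)
  }
  low_maf <- stats$maf < maf_min
  off_hwe <- stats$hwe_p < hwe_alpha
  removed <- off_chrom | low_maf | off_hwe
  reason <- rep(NA_character_, nrow(stats))
  reason[off_hwe] <- "hwe"
  reason[low_maf] <- "maf"
  reason[low_maf & off_hwe] <- "maf;hwe"
  reason[off_chrom] <- "chromosome"
  report <- mutate(
    stats,
    chrom = g$variants$chrom, pos_bp = g$variants$pos_bp,
    removed = removed, reason = reason
  )
  if (all(removed)) abort("quality control removed every variant")
  keep <- !removed
  out <- genotype_matrix(
    g$dosages[, keep, drop = FALSE], g$variants[keep, ],
    g$sample_ids, sort = FALSE
  )
  list(genotypes = out, report = report)
}

#' Write a QC report to TSV
#'
#' @param report the `report` element returned by [apply_qc()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  write.table(as.data.frame(report), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Derive de-regressed-proof reliabilities and weights
#'
#' Completes a trait table with the shrinkage factor `lambda_shrink =
#' (1 - h2) / h2`, the effective record contribution
#' `erc = lambda * REL / (1 - REL)` and the DRP reliability
#' `r2_drp = erc / (erc + lambda)`. The chain implies `r2_drp == rel_ebv`
#' algebraically; all three quantities are kept because downstream weighting
#' consumes them separately.
#'
#' @param traits tibble with columns `sample_id`, `drp`, `rel_ebv`
#'   (EBV reliability, strictly inside (0,1)) and `h2` (trait heritability).
#' @return the input tibble with `lambda_shrink`, `erc` and `r2_drp` added.
#' @export
derive_trait_weights <- function(traits) {
  traits <- as_tibble(traits)
  need <- c("sample_id", "drp", "rel_ebv", "h2")
  if (!all(need %in% names(traits))) {
    abort(paste("trait table must have columns:", paste(need, collapse = ", ")))
  }
  if (any(traits$h2 <= 0 | traits$h2 >= 1)) {
    abort("heritability must lie strictly inside (0, 1)")
  }
  if (any(traits$rel_ebv >= 1)) {
    abort("rel_ebv = 1 makes ERC = lambda * REL / (1 - REL) divide by zero")
  }
  if (any(traits$rel_ebv <= 0)) abort("rel_ebv must be strictly positive")
  mutate(
    traits,
    lambda_shrink = (1 - .data$h2) / .data$h2,
    erc = .data$lambda_shrink * .data$rel_ebv / (1 - .data$rel_ebv),
    r2_drp = .data$erc / (.data$erc + .data$lambda_shrink)
  )
}

#' Read a trait table of de-regressed proofs
#'
#' @param path CSV or TSV (delimiter sniffed from the header line) with
#'   columns `sample_id`, `drp`, `rel_ebv` and either an
#'   `h2` column or a scalar heritability passed as `h2`.
#' @param h2 trait heritability used when the file has no `h2` column.
#' @return tibble completed by [derive_trait_weights()].
#' @export
read_trait_table <- function(path, h2 = NULL) {
  header <- readLines(path, n = 1)
  sep <- if (grepl("\t", header)) "\t" else ","
  tab <- as_tibble(read.csv(path, sep = sep, stringsAsFactors = FALSE))
  if (!"h2" %in% names(tab)) {
    if (is.null(h2)) abort("supply h2: the file has no heritability column")
    tab$h2 <- h2
  }
  derive_trait_weights(tab)
}
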