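#' Encode raw allele calls as a minor-allele count matrix
#'
#' Per SNP, the minor allele is the less frequent allele among non-missing
#' calls (a 50/50 tie goes to the lexicographically smaller allele character,
#' so that the encoding is deterministic). The encoded value is the count of
#' the minor allele (0, 1 or 2); missing calls are `NA`. PCA downstream is
#' invariant to which allele is counted, since columns are later centred.
#'
#' @param raw A [raw_genotype_table()].
#' @param labels Named character vector mapping every sample id to a breed
#'   (as from [read_labels()]).
#' @return An object of class `genotype_matrix`: list with `values`
#'   (samples x SNPs numeric matrix, `NA` = missing), `labels`,
#'   `minor_allele`, `major_allele`, `maf` (all named by SNP),
#'   `monomorphic` (logical; single-allele or all-missing SNPs), plus
#'   `chrom`/`pos` carried through for export.
#' @export
encode <- function(raw, labels) {
  stopifnot(inherits(raw, "raw_genotype_table"))
  missing_lab <- setdiff(raw$sample_ids, names(labels))
  if (length(missing_lab)) {
    stop("no breed label for samples: ",
         paste(missing_lab, collapse = ", "), call. = FALSE)
  }
  labels <- labels[raw$sample_ids]
  n <- length(raw$sample_ids)
  m <- length(raw$snp_ids)
  values <- matrix(NA_real_, n, m,
                   dimnames = list(raw$sample_ids, raw$snp_ids))
  minor <- setNames(rep(NA_character_, m), raw$snp_ids)
  major <- minor
  maf <- setNames(rep(NA_real_, m), raw$snp_ids)
  mono <- setNames(rep(FALSE, m), raw$snp_ids)

  for (j in seq_len(m)) {
    x1 <- raw$a1[, j]
    x2 <- raw$a2[, j]
    miss <- x1 == "0"
    al <- c(x1[!miss], x2[!miss])
    ual <- sort(unique(al))
    if (length(ual) > 2L) {
      stop(sprintf("SNP %s has more than two alleles (%s)",
                   raw$snp_ids[j], paste(ual, collapse = ", ")),
           call. = FALSE)
    }
    if (length(ual) == 0L) { # all calls missing
      mono[j] <- TRUE
      next
    }
    if (length(ual) == 1L) {
      mono[j] <- TRUE
      minor[j] <- ual
      major[j] <- ual
      maf[j] <- 0
      values[!miss, j] <- 0
      next
    }
    f1 <- mean(al == ual[1])
    mi <- if (f1 <= 0.5) ual[1] else ual[2] # tie -> lexicographically smaller
    minor[j] <- mi
    major[j] <- setdiff(ual, mi)
    maf[j] <- min(f1, 1 - f1)
    values[!miss, j] <- (x1[!miss] == mi) + (x2[!miss] == mi)
  }

  structure(
    list(values = values, labels = labels, minor_allele = minor,
         major_allele = major, maf = maf, monomorphic = mono,
         chrom = raw$chrom, pos = raw$pos),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "genotype_matrix: %d samples x %d SNPs, %d breeds, %.2f%% missing\n",
    nrow(x$values), ncol(x$values), length(unique(x$labels)),
    100 * mean(is.na(x$values))
  ))
  invisible(x)
}

# keep a subset of SNP columns, preserving all per-SNP metadata
subset_snps <- function(gm, keep) {
  gm$values <- gm$values[, keep, drop = FALSE]
  gm$minor_allele <- gm$minor_allele[keep]
  gm$major_allele <- gm$major_allele[keep]
  gm$maf <- gm$maf[keep]
  gm$monomorphic <- gm$monomorphic[keep]
  gm$chrom <- gm$chrom[keep]
  gm$pos <- gm$pos[keep]
  gm
}

#' Remove high-missingness and monomorphic SNPs
#'
#' Drops every SNP whose missing-call fraction is strictly greater than
#' `max_missing_fraction` (so a SNP missing exactly the threshold fraction is
#' retained), then drops SNPs that are monomorphic among the remaining
#' non-missing calls (zero-variance columns carry no structure and would
#' break out-of-sample scaling). Samples are never removed. Idempotent.
#'
#' @param gm A `genotype_matrix` from [encode()].
#' @param max_missing_fraction Missingness threshold in `[0, 1)`;
#'   default 0.10.
#' @return The filtered `genotype_matrix`, with an attribute `qc` listing the
#'   number of SNPs dropped by each rule.
#' @export
filter_missing <- function(gm, max_missing_fraction = 0.10) {
  stopifnot(inherits(gm, "genotype_matrix"))
  check_prob(max_missing_fraction, "max_missing_fraction", 0, 1, open_hi = TRUE)
  miss_frac <- colMeans(is.na(gm$values))
  keep_miss <- miss_frac <= max_missing_fraction
  poly <- vapply(seq_len(ncol(gm$values)), function(j) {
    v <- gm$values[, j]
    v <- v[!is.na(v)]
    length(v) > 0L && any(v != v[1])
  }, logical(1))
  keep <- keep_miss & poly & !gm$monomorphic
  out <- subset_snps(gm, keep)
  attr(out, "qc") <- list(
    n_input = length(keep),
    n_dropped_missing = sum(!keep_miss),
    n_dropped_monomorphic = sum(keep_miss & !(poly & !gm$monomorphic)),
    n_kept = sum(keep)
  )
  out
}

#' Mean-impute missing entries and centre columns
#'
#' Missing entries are replaced by the column mean of the non-missing
#' entries, then every column is centred to mean zero. The column means are
#' kept as an attribute for out-of-sample projection: a new individual is
#' imputed and centred with the *training* means, never its own.
#'
#' @param x A `genotype_matrix` or a plain numeric matrix with `NA` missing
#'   entries and SNP column names. Columns must not be entirely missing.
#' @return Numeric matrix with attributes `column_means` (named numeric) and
#'   class `centered_genotypes`.
#' @export
center_impute <- function(x) {
  if (inherits(x, "genotype_matrix")) x <- x$values
  stopifnot(is.matrix(x), !is.null(colnames(x)))
  n_ok <- colSums(!is.na(x))
  if (any(n_ok == 0L)) {
    stop("columns entirely missing: ",
         paste(colnames(x)[n_ok == 0L], collapse = ", "), call. = FALSE)
  }
  cm <- colMeans(x, na.rm = TRUE)
  idx <- which(is.na(x))
  if (length(idx)) x[idx] <- cm[(idx - 1L) %/% nrow(x) + 1L]
  x <- x - rep(cm, each = nrow(x))
  attr(x, "column_means") <- cm
  x
}
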