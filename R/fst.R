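#' Multi-SNP Weir-Cockerham FST estimator
#'
#' Ratio-of-averages estimator of the fixation index over a set of biallelic
#' SNPs: per SNP the variance components `a` (among populations), `b` (among
#' individuals within populations) and `c` (within individuals) of Weir &
#' Cockerham (1984) are computed from genotype counts, and the estimate is
#' `sum(a) / sum(a + b + c)` over all usable SNPs. Used as the realised-drift
#' QC statistic for [simulate_dataset()].
#'
#' @param x A `genotype_matrix` (its `labels` are used unless `pops` is
#'   given), or a numeric sample-by-SNP dosage matrix in `{0, 1, 2}` with
#'   `NA` for missing calls.
#' @param pops Character or factor of population labels, one per row of the
#'   dosage matrix.
#' @return The multi-SNP FST estimate (a single number). SNPs represented in
#'   fewer than two populations, or monomorphic overall, contribute nothing.
#' @references Weir, B.S. and Cockerham, C.C. (1984) Estimating F-statistics
#'   for the analysis of population structure. Evolution 38:1358-1370.
#' @export
wc_fst <- function(x, pops = NULL) {
  if (inherits(x, "genotype_matrix")) {
    pops <- pops %||% unname(x$labels[rownames(x$values)])
    x <- x$values
  }
  if (is.null(pops)) stop("`pops` is required for a plain matrix", call. = FALSE)
  pops <- as.factor(pops)
  if (nlevels(pops) < 2L) stop("need at least two populations", call. = FALSE)
  stopifnot(length(pops) == nrow(x))

  num <- 0
  den <- 0
  for (j in seq_len(ncol(x))) {
    g <- x[, j]
    ok <- !is.na(g)
    if (!any(ok)) next
    gt <- g[ok]
    pp <- pops[ok]
    n_r <- tapply(gt, pp, length)
    keep <- !is.na(n_r) & n_r > 0
    if (sum(keep) < 2L) next
    n_r <- n_r[keep]
    p_r <- tapply(gt, pp, mean)[keep] / 2
    h_r <- tapply(gt == 1, pp, mean)[keep]
    r <- length(n_r)
    nbar <- mean(n_r)
    if (nbar <= 1) next
    nsum <- sum(n_r)
    nc <- (nsum - sum(n_r^2) / nsum) / (r - 1)
    if (nc <= 0) next
    pbar <- sum(n_r * p_r) / nsum
    if (pbar <= 0 || pbar >= 1) next
    s2 <- sum(n_r * (p_r - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n_r * h_r) / nsum

    a <- nbar / nc *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- nbar / (nbar - 1) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    num <- num + a
    den <- den + a + b + cc
  }
  if (den == 0) return(NA_real_)
  num / den
}
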