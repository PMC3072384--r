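#' PCA scores (leverage scores) for every SNP
#'
#' The PCA score of SNP `j` is the squared Euclidean norm of its row in the
#' top-k right-singular-vector matrix: `p_j = sum_i V[j, i]^2`. It measures
#' the degree of correlation between the SNP and the significant principal
#' components (the SNP's leverage on the dominant subspace). Scores are
#' non-negative and sum exactly to `k`.
#'
#' @param basis A `pc_basis` from [fit_pca()].
#' @param weighted If `TRUE`, weight each component by its squared singular
#'   value (off by default; the unweighted leverage is the standard form).
#' @return Data frame with columns `snp_id` and `score`, in basis SNP order,
#'   with attribute `k`.
#' @export
pcaim_scores <- function(basis, weighted = FALSE) {
  stopifnot(inherits(basis, "pc_basis"))
  V2 <- basis$V^2
  score <- if (weighted) {
    w <- basis$sigma^2 / sum(basis$sigma^2)
    as.numeric(V2 %*% w) * basis$k
  } else {
    rowSums(V2)
  }
  out <- data.frame(snp_id = basis$snp_ids, score = score,
                    stringsAsFactors = FALSE)
  attr(out, "k") <- basis$k
  out
}

#' Retain the top-scoring candidate SNPs
#'
#' @param scores Score table from [pcaim_scores()].
#' @param n_top Number of SNPs to retain.
#' @return Character vector of `n_top` SNP ids in descending score order
#'   (score ties broken by lexicographic SNP id, for determinism).
#' @export
top_candidates <- function(scores, n_top) {
  n_top <- check_count(n_top, "n_top")
  if (n_top > nrow(scores)) {
    stop(sprintf("n_top = %d exceeds the %d scored SNPs", n_top, nrow(scores)),
         call. = FALSE)
  }
  ord <- order(-scores$score, scores$snp_id)
  scores$snp_id[ord[seq_len(n_top)]]
}

#' Greedy column subset selection (redundancy removal)
#'
#' Deterministic greedy column-pivoted QR (Businger-Golub) on the centred
#' candidate matrix: at each step the column with the largest residual norm
#' — after projecting out the columns already chosen — is selected, so a
#' marker that is an (exact or near) duplicate of an already-selected marker
#' has (near-)zero residual and is skipped while independent informative
#' columns remain. Selection order is the pivot order, hence truncations at
#' different `c` are nested prefixes. Residual-norm ties (within a relative
#' 1e-9) break toward the lexicographically smaller SNP id.
#'
#' @param x Centred samples x candidates matrix with SNP column names.
#' @param k Number of significant components at the node; used to validate
#'   that the candidate matrix carries at least `k` dimensions of structure.
#' @param c Number of columns to select, `c <= ncol(x)`.
#' @return Character vector of `c` selected SNP ids in pivot order.
#' @export
cssp_select <- function(x, k, c) {
  stopifnot(is.matrix(x), !is.null(colnames(x)))
  c <- check_count(c, "c")
  k <- check_count(k, "k")
  p <- ncol(x)
  if (c > p) stop(sprintf("c = %d exceeds the %d candidates", c, p), call. = FALSE)
  nrm <- colSums(x^2)
  if (max(nrm) <= 0) stop("degenerate input: all candidate columns are zero",
                          call. = FALSE)
  d <- svd(x, nu = 0, nv = 0)$d
  rank <- sum(d > d[1] * 1e-12)
  if (k > rank) {
    stop(sprintf("k = %d exceeds candidate-matrix rank %d", k, rank),
         call. = FALSE)
  }
  ids <- colnames(x)
  R <- x # residual matrix, updated in place
  selected <- character(c)
  avail <- rep(TRUE, p)
  for (s in seq_len(c)) {
    cand <- which(avail)
    mx <- max(nrm[cand])
    tie <- cand[nrm[cand] >= mx - 1e-9 * max(mx, 1e-300)]
    j <- tie[order(ids[tie])][1]
    selected[s] <- ids[j]
    avail[j] <- FALSE
    if (mx > 1e-24) {
      q <- R[, j] / sqrt(nrm[j])
      coef <- crossprod(q, R) # 1 x p
      R <- R - q %*% coef
      R[, j] <- 0
      nrm <- pmax(nrm - as.numeric(coef)^2, 0)
      nrm[j] <- 0
    }
  }
  selected
}

#' Ranked, nested SNP marker panels for a decision-tree node
#'
#' @param node Node name the panel belongs to.
#' @param snp_ids SNP ids in selection (pivot) order, no duplicates.
#' @param tiers Named integer vector of nested tier sizes, e.g.
#'   `c(P1 = 50, P2 = 100, P3 = 150)`; must be non-decreasing with the
#'   largest tier equal to `length(snp_ids)`. Tiers are prefixes, so
#'   `P1` is a subset of `P2` is a subset of `P3` by construction.
#' @param scores Named numeric PCA scores covering `snp_ids`.
#' @return Object of class `snp_panel`.
#' @export
snp_panel <- function(node, snp_ids, tiers, scores) {
  if (anyDuplicated(snp_ids)) stop("panel has duplicate SNP ids", call. = FALSE)
  tiers <- setNames(as.integer(tiers), names(tiers))
  if (is.unsorted(tiers)) stop("tier sizes must be non-decreasing", call. = FALSE)
  if (tiers[length(tiers)] != length(snp_ids)) {
    stop("largest tier must equal the panel length", call. = FALSE)
  }
  if (!all(snp_ids %in% names(scores))) {
    stop("scores must cover every panel SNP", call. = FALSE)
  }
  structure(
    list(node = node, snp_ids = snp_ids, tiers = tiers,
         scores = scores[snp_ids]),
    class = "snp_panel"
  )
}

#' @export
print.snp_panel <- function(x, ...) {
  cat(sprintf("snp_panel at node '%s': tiers %s\n", x$node,
              paste(sprintf("%s=%d", names(x$tiers), x$tiers), collapse = " ")))
  invisible(x)
}

#' Build nested marker panels at a node
#'
#' Ranks all SNPs by PCA score, keeps the `n_top` best candidates, then runs
#' greedy column subset selection on the candidate submatrix to order them
#' with redundancy removed. The panel tiers P1/P2/P3 are prefixes of the
#' selection order with sizes `p1_size`, `2*p1_size`, `3*p1_size` (or any
#' explicit non-decreasing `tier_sizes`, e.g. `c(10, 25, 50)`).
#'
#' @param x Centred node matrix from [center_impute()].
#' @param basis The node's full-SNP `pc_basis`.
#' @param n_top Candidate pool size (must be at least the largest tier).
#' @param p1_size Size of the smallest tier (ignored if `tier_sizes` given).
#' @param tier_sizes Optional explicit tier sizes (named or not; names
#'   default to P1/P2/P3).
#' @param node Node name recorded in the panel.
#' @return An [snp_panel()].
#' @export
build_panels <- function(x, basis, n_top, p1_size = NULL, tier_sizes = NULL,
                         node = "node") {
  stopifnot(inherits(basis, "pc_basis"))
  if (is.null(tier_sizes)) {
    p1_size <- check_count(p1_size, "p1_size")
    tier_sizes <- c(P1 = p1_size, P2 = 2L * p1_size, P3 = 3L * p1_size)
  } else {
    tier_sizes <- as.integer(tier_sizes)
    if (is.null(names(tier_sizes)) || !all(nzchar(names(tier_sizes)))) {
      names(tier_sizes) <- paste0("P", seq_along(tier_sizes))
    }
  }
  cmax <- max(tier_sizes)
  if (cmax > n_top) {
    stop(sprintf("largest tier (%d) exceeds the candidate pool n_top = %d",
                 cmax, n_top), call. = FALSE)
  }
  scores <- pcaim_scores(basis)
  cand <- top_candidates(scores, n_top)
  xc <- x[, cand, drop = FALSE]
  k_eff <- min(basis$k, nrow(xc) - 1L, ncol(xc))
  sel <- cssp_select(xc, k = k_eff, c = cmax)
  snp_panel(node = node, snp_ids = sel, tiers = tier_sizes,
            scores = setNames(scores$score, scores$snp_id))
}
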