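#' PC basis fitted at a decision-tree node
#'
#' Holds the top-k right singular vectors (SNP loadings) of a centred
#' genotype matrix, the corresponding singular values, and the column means
#' used for centring/imputation, so out-of-sample individuals can be
#' projected consistently.
#'
#' @param V n_snps x k matrix of right singular vectors (orthonormal columns).
#' @param sigma Positive, non-increasing singular values, length k.
#' @param column_means Per-SNP means used for centring (named).
#' @param k Number of significant principal components.
#' @param snp_ids SNP order of the rows of `V`.
#' @return Object of class `pc_basis`.
#' @keywords internal
pc_basis <- function(V, sigma, column_means, k, snp_ids) {
  stopifnot(ncol(V) == k, length(sigma) == k, nrow(V) == length(snp_ids))
  if (any(sigma <= 0) || is.unsorted(rev(sigma))) {
    stop("singular values must be positive and non-increasing", call. = FALSE)
  }
  rownames(V) <- snp_ids
  structure(
    list(V = V, sigma = sigma,
         column_means = setNames(as.numeric(column_means), snp_ids),
         k = k, snp_ids = snp_ids),
    class = "pc_basis"
  )
}

#' @export
print.pc_basis <- function(x, ...) {
  cat(sprintf("pc_basis: %d SNPs, k = %d, sigma = [%s]\n",
              length(x$snp_ids), x$k,
              paste(signif(x$sigma, 4), collapse = ", ")))
  invisible(x)
}

#' Fit PCA on a centred genotype matrix
#'
#' Computes the top-k singular triplets of the centred matrix `A = U S V'`.
#' Training coordinates are `A \%*\% V_k` (equivalently `U_k diag(sigma)`).
#' The sign of each singular vector is fixed so that its largest-magnitude
#' loading is positive; all downstream quantities (distances, squared
#' loadings) are sign-invariant anyway, this only makes reruns bit-stable.
#'
#' @param x Centred matrix from [center_impute()].
#' @param k Number of components, `1 <= k <= rank(x)`.
#' @param column_means Per-SNP means (defaults to the attribute set by
#'   [center_impute()]).
#' @return List with `basis` (a `pc_basis`) and `coords` (samples x k
#'   training coordinates).
#' @export
fit_pca <- function(x, k, column_means = attr(x, "column_means")) {
  stopifnot(is.matrix(x))
  if (is.null(column_means)) {
    stop("`column_means` missing; pass the matrix produced by center_impute()",
         call. = FALSE)
  }
  k <- check_count(k, "k")
  sv <- svd(x)
  rank <- sum(sv$d > max(sv$d[1], 0) * 1e-12)
  if (rank == 0L) stop("matrix is numerically zero", call. = FALSE)
  if (k > rank) {
    stop(sprintf("k = %d exceeds matrix rank %d", k, rank), call. = FALSE)
  }
  V <- sv$v[, seq_len(k), drop = FALSE]
  for (i in seq_len(k)) { # deterministic sign convention
    j <- which.max(abs(V[, i]))
    if (V[j, i] < 0) V[, i] <- -V[, i]
  }
  coords <- x %*% V
  rownames(coords) <- rownames(x)
  list(
    basis = pc_basis(V, sv$d[seq_len(k)], column_means, k, colnames(x)),
    coords = coords
  )
}

#' Project samples onto a fitted PC basis
#'
#' Restricts each sample to the basis SNP set, imputes missing entries with
#' the training column means, centres with the same means, and multiplies by
#' the loading matrix. A sample with every call missing therefore projects
#' exactly to the origin.
#'
#' @param basis A `pc_basis`.
#' @param values Named numeric vector (one sample) or matrix with SNP column
#'   names; `NA` marks missing calls. Must cover every basis SNP.
#' @return Coordinates: a samples x k matrix (a 1-row matrix for a vector
#'   input).
#' @export
project_samples <- function(basis, values) {
  stopifnot(inherits(basis, "pc_basis"))
  if (is.null(dim(values))) {
    values <- matrix(values, nrow = 1, dimnames = list(NULL, names(values)))
  }
  missing_ids <- setdiff(basis$snp_ids, colnames(values))
  if (length(missing_ids)) {
    stop("sample is missing SNPs required by the basis: ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  }
  x <- values[, basis$snp_ids, drop = FALSE]
  idx <- which(is.na(x))
  if (length(idx)) x[idx] <- basis$column_means[(idx - 1L) %/% nrow(x) + 1L]
  x <- x - rep(basis$column_means, each = nrow(x))
  x %*% basis$V
}

# leave-one-out k-NN majority-vote accuracy in a fixed coordinate space;
# ties in distance broken by sample id for determinism
loo_knn_accuracy <- function(coords, labels, k_nn = 5L) {
  n <- nrow(coords)
  ids <- rownames(coords) %||% sprintf("s%06d", seq_len(n))
  d <- as.matrix(dist(coords))
  correct <- logical(n)
  for (i in seq_len(n)) {
    di <- d[i, -i]
    oid <- ids[-i]
    ord <- order(di, oid)
    kk <- min(k_nn, length(ord))
    nn <- ord[seq_len(kk)]
    maj <- ceiling(kk / 2)
    tab <- sort(table(labels[-i][nn]), decreasing = TRUE)
    correct[i] <- tab[1] >= maj && names(tab)[1] == labels[i]
  }
  mean(correct)
}

#' Choose the number of significant principal components
#'
#' Returns the smallest `k` among the candidates that maximises leave-one-out
#' 5-NN classification accuracy of the breed labels in the space of the first
#' `k` principal components (the same cross-validation device used to
#' evaluate the classifier; ties break toward smaller `k`).
#'
#' A candidate `k` is only considered when the spectrum has a relative gap
#' `(sigma_k - sigma_{k+1}) / sigma_1` of at least `spectral_gap_tol`:
#' cutting inside a (near-)degenerate multiplet of singular values yields a
#' subspace whose individual axes rotate freely under resampling, so the
#' in-sample coordinates overstate how reproducible such a basis is. If no
#' candidate has a gap, all candidates are considered.
#'
#' @param x Centred matrix from [center_impute()].
#' @param labels Breed label per row of `x` (at least two distinct breeds).
#' @param k_candidates Candidate values of `k`; candidates exceeding the
#'   matrix rank are dropped.
#' @param k_nn Neighbours for the vote (default 5).
#' @param spectral_gap_tol Minimum relative singular-value gap for a
#'   candidate to be stable (default 0.02).
#' @return The chosen `k` (integer).
#' @export
choose_num_pcs <- function(x, labels, k_candidates = 1:6, k_nn = 5L,
                           spectral_gap_tol = 0.02) {
  stopifnot(is.matrix(x), length(labels) == nrow(x))
  if (length(unique(labels)) < 2L) {
    stop("need at least two breeds to choose k", call. = FALSE)
  }
  if (length(k_candidates) < 1L) stop("k_candidates is empty", call. = FALSE)
  k_candidates <- sort(unique(as.integer(k_candidates)))
  sv <- svd(x)
  rank <- sum(sv$d > max(sv$d[1], 0) * 1e-12)
  if (rank == 0L) stop("degenerate (zero) matrix", call. = FALSE)
  k_candidates <- k_candidates[k_candidates >= 1L & k_candidates <= rank]
  if (length(k_candidates) == 0L) {
    stop("no candidate k is within the matrix rank", call. = FALSE)
  }
  d_next <- c(sv$d[-1], 0)
  gap <- (sv$d - d_next) / sv$d[1]
  stable <- k_candidates[gap[k_candidates] >= spectral_gap_tol]
  if (length(stable)) k_candidates <- stable
  kmax <- max(k_candidates)
  coords <- x %*% sv$v[, seq_len(kmax), drop = FALSE]
  rownames(coords) <- rownames(x)
  acc <- vapply(
    k_candidates,
    function(k) loo_knn_accuracy(coords[, seq_len(k), drop = FALSE], labels, k_nn),
    numeric(1)
  )
  k_candidates[which.max(acc)] # which.max -> first (smallest k) on ties
}

#' Export PC coordinates as a TSV for plotting
#'
#' @param coords Samples x k coordinate matrix (rownames = sample ids).
#' @param labels Named breed labels.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_pc_coords <- function(coords, labels, path) {
  df <- data.frame(
    sample_id = rownames(coords),
    breed = unname(labels[rownames(coords)]),
    coords, check.names = FALSE
  )
  colnames(df)[-(1:2)] <- paste0("PC", seq_len(ncol(coords)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
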