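# Shared fixtures and independent oracle implementations.
# Oracles deliberately take a different computational route than the package
# (eigendecomposition of the Gram matrix instead of SVD, explicit projection
# via QR instead of greedy pivoting, exhaustive enumeration, ...).

# two-level six-breed study conditions used by the end-to-end experiments
two_level_spec <- function(seed = 42L, n_per_breed = 40L, n_snps = 2000L) {
  breed_tree_spec(
    nodes = list(g1 = c("B1", "B2", "B3"), g2 = c("B4", "B5", "B6")),
    branch_fst = c(0.15, 0.05),
    n_per_breed = n_per_breed, n_snps = n_snps,
    missing_rate = 0.05,
    redundancy_factor = 3L, redundancy_fraction = 0.2,
    redundancy_flip_prob = 0.05,
    seed = seed
  )
}

# smaller 2x2 version for replicated LOOCV experiments
small_two_level_spec <- function(seed) {
  breed_tree_spec(
    nodes = list(g1 = c("B1", "B2"), g2 = c("B3", "B4")),
    branch_fst = c(0.15, 0.05),
    n_per_breed = 15L, n_snps = 800L,
    missing_rate = 0.05,
    redundancy_factor = 3L, redundancy_fraction = 0.2,
    redundancy_flip_prob = 0.05,
    seed = seed
  )
}

two_breed_spec <- function(fst = 0.4, n_per_breed = 30L, n_snps = 500L,
                           seed = 1L, ...) {
  breed_tree_spec(nodes = c("A", "B"), branch_fst = fst,
                  n_per_breed = n_per_breed, n_snps = n_snps, seed = seed, ...)
}

# random centred matrix with ids (already mean-zero by construction check)
rand_centered <- function(n, m, seed) {
  set.seed(seed)
  x <- matrix(rnorm(n * m), n, m,
              dimnames = list(sprintf("i%03d", seq_len(n)),
                              sprintf("c%03d", seq_len(m))))
  x <- x - rep(colMeans(x), each = n)
  attr(x, "column_means") <- setNames(numeric(m), colnames(x))
  x
}

# --- oracle: PCA scores via eigendecomposition of the Gram matrix ---------
# p_j = sum_i (u_i' a_j)^2 / lambda_i over the top-k eigenpairs of A A'
score_oracle <- function(x, k) {
  e <- eigen(tcrossprod(x), symmetric = TRUE)
  U <- e$vectors[, seq_len(k), drop = FALSE]
  lam <- e$values[seq_len(k)]
  b <- crossprod(U, x) # k x m
  colSums(b^2 / lam)
}

# --- oracle: Frobenius error of reconstructing x from a column subset -----
recon_error <- function(x, ids) {
  S <- x[, ids, drop = FALSE]
  fit <- qr.fitted(qr(S), x)
  sqrt(sum((x - fit)^2))
}

# exhaustive optimum over all c-subsets (small instances only)
best_subset_error <- function(x, c) {
  combos <- utils::combn(ncol(x), c)
  min(apply(combos, 2, function(j) recon_error(x, j)))
}

# --- tiny hand-written PED/MAP fixture ------------------------------------
write_tiny_pedmap <- function(dir) {
  ped <- file.path(dir, "tiny.ped")
  map <- file.path(dir, "tiny.map")
  writeLines(c(
    "F1 S1 0 0 0 -9 A A A G G G",
    "F2 S2 0 0 0 -9 A A G G 0 0"
  ), ped)
  writeLines(c(
    "1\tsnpA\t0\t100",
    "1\tsnpB\t0\t200",
    "1\tsnpC\t0\t300"
  ), map)
  list(ped = ped, map = map)
}
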