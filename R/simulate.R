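#' Specify a hierarchical multi-breed genotype simulation
#'
#' Describes a synthetic diploid SNP dataset with a planted population
#' hierarchy. Allele frequencies drift along each branch of the hierarchy
#' under the Balding-Nichols model: a child population's frequency is drawn
#' from `Beta(p(1-F)/F, (1-p)(1-F)/F)` around its parent's frequency `p`,
#' where `F` is the branch differentiation (FST) parameter. Linkage
#' disequilibrium is emulated by duplicating a fraction of SNPs with optional
#' per-entry corruption, and missing calls are introduced completely at
#' random.
#'
#' @param nodes Nested grouping of breed names: either a character vector of
#'   breed names (a flat hierarchy, one level) or a named list whose elements
#'   are themselves groupings (character vectors or deeper lists). Breed names
#'   must be unique across the tree.
#' @param branch_fst Numeric vector of per-level FST values in (0, 1); element
#'   `d` applies to every branch at depth `d` (the last element is recycled
#'   for deeper levels).
#' @param n_per_breed Individuals simulated per breed.
#' @param n_snps Number of base SNPs (before duplication).
#' @param ancestral_freq_range Length-2 numeric `(lo, hi)` with
#'   `0 < lo < hi < 1`; ancestral frequencies are drawn uniformly from it.
#' @param missing_rate Per-genotype missing-call probability in `[0, 1)`.
#' @param redundancy_factor Integer `r >= 1`: each duplicated SNP appears
#'   `r - 1` extra times (so `r = 1` disables duplication).
#' @param redundancy_fraction Fraction of base SNPs that receive duplicates.
#' @param redundancy_flip_prob Per-entry probability, in `[0, 0.5)`, that a
#'   duplicated genotype is resampled from the breed frequency instead of
#'   copied (imperfect LD).
#' @param seed Integer seed; identical seeds give bit-identical datasets.
#' @return An object of class `breed_tree_spec`.
#' @seealso [simulate_dataset()]
#' @export
breed_tree_spec <- function(nodes, branch_fst, n_per_breed, n_snps,
                            ancestral_freq_range = c(0.1, 0.9),
                            missing_rate = 0,
                            redundancy_factor = 1L,
                            redundancy_fraction = 0.2,
                            redundancy_flip_prob = 0,
                            seed = 1L) {
  breeds <- tree_leaves(nodes)
  if (length(breeds) < 1L) stop_field("nodes", "must contain at least one breed")
  if (anyDuplicated(breeds)) {
    stop_field("nodes", sprintf(
      "breed names must be unique (duplicated: %s)",
      paste(unique(breeds[duplicated(breeds)]), collapse = ", ")
    ))
  }
  if (!is.numeric(branch_fst) || length(branch_fst) < 1L ||
      any(branch_fst <= 0) || any(branch_fst >= 1)) {
    stop_field("branch_fst", "all values must lie in (0, 1)")
  }
  n_per_breed <- check_count(n_per_breed, "n_per_breed")
  n_snps <- check_count(n_snps, "n_snps", min = 1L)
  if (!is.numeric(ancestral_freq_range) || length(ancestral_freq_range) != 2L ||
      ancestral_freq_range[1] <= 0 || ancestral_freq_range[2] >= 1 ||
      ancestral_freq_range[1] >= ancestral_freq_range[2]) {
    stop_field("ancestral_freq_range", "must be (lo, hi) with 0 < lo < hi < 1")
  }
  check_prob(missing_rate, "missing_rate", 0, 1, open_hi = TRUE)
  redundancy_factor <- check_count(redundancy_factor, "redundancy_factor")
  check_prob(redundancy_fraction, "redundancy_fraction", 0, 1)
  check_prob(redundancy_flip_prob, "redundancy_flip_prob", 0, 0.5, open_hi = TRUE)
  seed <- check_count(seed, "seed", min = 0L)

  structure(
    list(
      nodes = nodes, branch_fst = as.numeric(branch_fst),
      n_per_breed = n_per_breed, n_snps = n_snps,
      ancestral_freq_range = as.numeric(ancestral_freq_range),
      missing_rate = missing_rate,
      redundancy_factor = redundancy_factor,
      redundancy_fraction = redundancy_fraction,
      redundancy_flip_prob = redundancy_flip_prob,
      seed = seed, breeds = breeds
    ),
    class = "breed_tree_spec"
  )
}

# leaves (breed names) of a nested grouping, in declaration order
tree_leaves <- function(nodes) {
  if (is.character(nodes)) return(nodes)
  if (!is.list(nodes)) stop_field("nodes", "must be a character vector or nested list")
  unlist(lapply(nodes, tree_leaves), use.names = FALSE)
}

#' @export
print.breed_tree_spec <- function(x, ...) {
  cat(sprintf(
    "breed_tree_spec: %d breeds, %d per breed, %d base SNPs (seed %d)\n",
    length(x$breeds), x$n_per_breed, x$n_snps, x$seed
  ))
  cat(sprintf(
    "  branch FST: %s | missing %.3g | redundancy x%d on %.0f%% (flip %.3g)\n",
    paste(signif(x$branch_fst, 3), collapse = "/"), x$missing_rate,
    x$redundancy_factor, 100 * x$redundancy_fraction, x$redundancy_flip_prob
  ))
  invisible(x)
}

# Balding-Nichols drift: child frequency around parent p with parameter F,
# clamped away from fixation so downstream frequencies stay in (0, 1).
drift_freq <- function(p, fst) {
  q <- stats::rbeta(length(p), p * (1 - fst) / fst, (1 - p) * (1 - fst) / fst)
  pmin(pmax(q, 0.01), 0.99)
}

# recursive walk assigning a drifted frequency vector to every breed
drift_tree <- function(nodes, p_parent, branch_fst, depth, out) {
  fst <- branch_fst[min(depth, length(branch_fst))]
  if (is.character(nodes)) {
    for (b in nodes) out[[b]] <- drift_freq(p_parent, fst)
    return(out)
  }
  for (child in nodes) {
    if (is.character(child) && length(child) == 1L) {
      out[[child]] <- drift_freq(p_parent, fst)
    } else {
      p_child <- drift_freq(p_parent, fst)
      out <- drift_tree(child, p_child, branch_fst, depth + 1L, out)
    }
  }
  out
}

#' Simulate a multi-breed diploid SNP dataset
#'
#' Draws ancestral frequencies uniformly from the spec's range, drifts them
#' along each hierarchy branch under Balding-Nichols, samples genotypes as
#' `Binomial(2, p_breed)` minor/alternate-allele counts, duplicates a fraction
#' of SNPs to create LD-redundant blocks (with optional per-entry corruption),
#' and finally masks entries as missing completely at random.
#'
#' @param spec A [breed_tree_spec()].
#' @return An object of class `sim_dataset`: a list with components
#'   \describe{
#'     \item{raw}{[raw_genotype_table()] of allele-character calls
#'       (alleles `"A"`/`"B"`, missing `"0"`).}
#'     \item{genotypes}{`genotype_matrix` from [encode()] (minor-allele
#'       counts with breed labels).}
#'     \item{truth}{list with `ancestral_freq`, `breed_freq`
#'       (breed x SNP matrix of drifted `"B"`-allele frequencies, duplicates
#'       inherit their base SNP's row), `dup_group` (named by SNP; the base
#'       SNP id of each duplicate group) and `labels`.}
#'     \item{spec}{the input spec.}
#'   }
#' @examples
#' spec <- breed_tree_spec(c("A", "B"), branch_fst = 0.2,
#'                         n_per_breed = 10, n_snps = 100, seed = 1)
#' sim <- simulate_dataset(spec)
#' dim(sim$genotypes$values)
#' @export
simulate_dataset <- function(spec) {
  if (!inherits(spec, "breed_tree_spec")) {
    stop("`spec` must be a breed_tree_spec", call. = FALSE)
  }
  set.seed(spec$seed)
  m0 <- spec$n_snps
  breeds <- spec$breeds
  n_b <- spec$n_per_breed
  n <- n_b * length(breeds)

  p_anc <- runif(m0, spec$ancestral_freq_range[1], spec$ancestral_freq_range[2])
  freq <- drift_tree(spec$nodes, p_anc, spec$branch_fst, 1L, list())
  freq <- do.call(rbind, freq[breeds]) # breeds x m0

  sample_ids <- unlist(lapply(breeds, function(b) sprintf("%s_%03d", b, seq_len(n_b))))
  labels <- setNames(rep(breeds, each = n_b), sample_ids)

  # base genotype matrix, minor/alt-allele ("B") dosage
  geno <- matrix(NA_real_, n, m0)
  for (i in seq_along(breeds)) {
    rows <- (i - 1L) * n_b + seq_len(n_b)
    geno[rows, ] <- matrix(
      rbinom(n_b * m0, 2L, rep(freq[i, ], each = n_b)), n_b, m0
    )
  }
  base_ids <- sprintf("snp%06d", seq_len(m0))

  # duplicate a fraction of base SNPs, placing copies next to their base SNP
  r <- spec$redundancy_factor
  n_dup <- if (r > 1L) floor(spec$redundancy_fraction * m0) else 0L
  dup_base <- if (n_dup > 0L) sort(sample.int(m0, n_dup)) else integer()
  n_copies <- integer(m0)
  n_copies[dup_base] <- r - 1L

  m <- m0 + sum(n_copies)
  values <- matrix(NA_real_, n, m)
  snp_ids <- character(m)
  src <- integer(m) # base-SNP index of every final column
  breed_of_row <- rep(seq_along(breeds), each = n_b)
  col <- 0L
  for (j in seq_len(m0)) {
    col <- col + 1L
    values[, col] <- geno[, j]
    snp_ids[col] <- base_ids[j]
    src[col] <- j
    for (t in seq_len(n_copies[j])) {
      col <- col + 1L
      g <- geno[, j]
      if (spec$redundancy_flip_prob > 0) {
        flip <- runif(n) < spec$redundancy_flip_prob
        if (any(flip)) {
          g[flip] <- rbinom(sum(flip), 2L, freq[cbind(breed_of_row[flip], j)])
        }
      }
      values[, col] <- g
      snp_ids[col] <- sprintf("%s_d%d", base_ids[j], t)
      src[col] <- j
    }
  }

  if (spec$missing_rate > 0) {
    values[runif(n * m) < spec$missing_rate] <- NA_real_
  }

  raw <- dosage_to_raw(values, sample_ids, labels, snp_ids)
  gm <- encode(raw, labels)

  truth <- list(
    ancestral_freq = setNames(p_anc[src], snp_ids),
    breed_freq = structure(freq[, src, drop = FALSE],
                           dimnames = list(breeds, snp_ids)),
    dup_group = setNames(base_ids[src], snp_ids),
    labels = labels
  )
  structure(list(raw = raw, genotypes = gm, truth = truth, spec = spec),
            class = "sim_dataset")
}

# dosage of allele "B" (NA = missing) -> raw allele-character table
dosage_to_raw <- function(values, sample_ids, labels, snp_ids) {
  n <- nrow(values); m <- ncol(values)
  a1 <- matrix("0", n, m)
  a2 <- matrix("0", n, m)
  ok <- !is.na(values)
  a1[ok] <- ifelse(values[ok] >= 1, "B", "A")
  a2[ok] <- ifelse(values[ok] == 2, "B", "A")
  raw_genotype_table(
    sample_ids = sample_ids,
    family_ids = unname(labels[sample_ids]),
    snp_ids = snp_ids,
    a1 = a1, a2 = a2,
    chrom = rep("1", m),
    pos = seq_len(m) * 1000L
  )
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf(
    "sim_dataset: %d samples x %d SNPs, %d breeds (seed %d)\n",
    nrow(x$genotypes$values), ncol(x$genotypes$values),
    length(unique(x$genotypes$labels)), x$spec$seed
  ))
  invisible(x)
}

#' Export a simulated dataset as plain-text fixture files
#'
#' Writes PLINK-style PED/MAP files, a sample-to-breed label table and a
#' per-SNP truth table into `directory`. The PED/MAP pair round-trips
#' losslessly through [read_genotypes()].
#'
#' @param sim A `sim_dataset` from [simulate_dataset()].
#' @param directory Target directory (created if needed).
#' @param prefix Basename for the output files.
#' @return Invisibly, a named character vector of the file paths written
#'   (`ped`, `map`, `labels`, `truth`).
#' @export
export_fixture <- function(sim, directory, prefix = "sim") {
  if (!inherits(sim, "sim_dataset")) stop("`sim` must be a sim_dataset", call. = FALSE)
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    ped = file.path(directory, paste0(prefix, ".ped")),
    map = file.path(directory, paste0(prefix, ".map")),
    labels = file.path(directory, paste0(prefix, "_labels.tsv")),
    truth = file.path(directory, paste0(prefix, "_truth.tsv"))
  )
  write_ped(sim$raw, paths[["ped"]], paths[["map"]])
  write_labels(sim$truth$labels, paths[["labels"]])

  truth_df <- data.frame(
    snp_id = sim$raw$snp_ids,
    dup_group = unname(sim$truth$dup_group[sim$raw$snp_ids]),
    ancestral_freq = unname(sim$truth$ancestral_freq[sim$raw$snp_ids]),
    t(sim$truth$breed_freq[, sim$raw$snp_ids, drop = FALSE]),
    check.names = FALSE,
    stringsAsFactors = FALSE
  )
  write.table(truth_df, paths[["truth"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}
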