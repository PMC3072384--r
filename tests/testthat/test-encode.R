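make_raw <- function(a1, a2, snp_ids = NULL, sample_ids = NULL) {
  n <- nrow(a1)
  m <- ncol(a1)
  raw_genotype_table(
    sample_ids = sample_ids %||% sprintf("S%d", seq_len(n)),
    family_ids = rep("F", n),
    snp_ids = snp_ids %||% sprintf("snp%d", seq_len(m)),
    a1 = a1, a2 = a2
  )
}
`%||%` <- function(x, y) if (is.null(x)) y else x

test_that("minor-allele counting follows the definition", {
  # calls AA, AA, AG, GG with G the rarer allele -> 0, 0, 1, 2
  raw <- make_raw(a1 = cbind(c("A", "A", "A", "G")),
                  a2 = cbind(c("A", "A", "G", "G")))
  gm <- encode(raw, setNames(rep("X", 4), raw$sample_ids))
  expect_identical(unname(gm$values[, 1]), c(0, 0, 1, 2))
  expect_identical(unname(gm$minor_allele[1]), "G")
  expect_equal(unname(gm$maf[1]), 3 / 8)
})

test_that("degenerate SNPs are flagged, >2 alleles are an error", {
  raw <- make_raw(
    a1 = cbind(c("0", "0"), c("A", "A")),
    a2 = cbind(c("0", "0"), c("A", "A")),
    snp_ids = c("allmiss", "mono")
  )
  gm <- encode(raw, setNames(rep("X", 2), raw$sample_ids))
  expect_true(gm$monomorphic[["allmiss"]])
  expect_true(gm$monomorphic[["mono"]])
  expect_true(all(is.na(gm$values[, "allmiss"])))

  raw3 <- make_raw(a1 = cbind(c("A", "C", "G")), a2 = cbind(c("A", "C", "G")),
                   snp_ids = "tri")
  expect_error(encode(raw3, setNames(rep("X", 3), raw3$sample_ids)), "tri")
})

test_that("a 50/50 allele tie goes to the lexicographically smaller allele", {
  raw <- make_raw(a1 = cbind(c("A", "G")), a2 = cbind(c("A", "G")))
  gm <- encode(raw, setNames(rep("X", 2), raw$sample_ids))
  expect_identical(unname(gm$minor_allele[1]), "A")
})

test_that("minor-allele frequency equals a brute-force allele count", {
  spec <- two_breed_spec(n_per_breed = 15L, n_snps = 60L, seed = 17L,
                         missing_rate = 0.1)
  sim <- simulate_dataset(spec)
  gm <- sim$genotypes
  for (s in sample(colnames(gm$values), 20)) {
    al <- c(sim$raw$a1[, s], sim$raw$a2[, s])
    al <- al[al != "0"]
    if (length(unique(al)) < 2) next
    counts <- table(al)
    expect_equal(unname(gm$maf[s]), min(counts) / sum(counts), label = s)
    expect_identical(unname(gm$minor_allele[s]),
                     names(counts)[which.min(counts)])
  }
})

test_that("the missingness filter is strict at the threshold and idempotent", {
  # 10 samples x 8 SNPs: snp k has k missing calls (k = 0..7)
  a1 <- matrix("A", 10, 8)
  a2 <- matrix("G", 10, 8) # every SNP heterozygous -> polymorphic
  a2[10, ] <- "A" # sample 10 homozygous, never missing -> variance survives
  for (k in seq_len(7)) {
    a1[seq_len(k), k + 1] <- "0"
    a2[seq_len(k), k + 1] <- "0"
  }
  raw <- make_raw(a1, a2)
  gm <- encode(raw, setNames(rep("X", 10), raw$sample_ids))
  filt <- filter_missing(gm, max_missing_fraction = 0.10)
  # boundary: snp2 has exactly 10% missing and is retained; > 10% removed
  expect_identical(colnames(filt$values), c("snp1", "snp2"))
  # independent recount
  frac <- colMeans(is.na(gm$values))
  expect_identical(ncol(filt$values), sum(frac <= 0.10))
  again <- filter_missing(filt, max_missing_fraction = 0.10)
  expect_identical(again$values, filt$values)
})

test_that("monomorphic columns are dropped at QC", {
  a1 <- cbind(c("A", "A", "A"), c("A", "A", "G"))
  a2 <- cbind(c("A", "A", "A"), c("A", "G", "G"))
  raw <- make_raw(a1, a2)
  gm <- encode(raw, setNames(rep("X", 3), raw$sample_ids))
  filt <- filter_missing(gm)
  expect_identical(colnames(filt$values), "snp2")
  expect_identical(attr(filt, "qc")$n_dropped_monomorphic, 1L)
})

test_that("center_impute does the arithmetic of the contract", {
  x <- cbind(a = c(0, 1, 2), b = c(0, NA, 2))
  rownames(x) <- c("r1", "r2", "r3")
  cx <- center_impute(x)
  expect_equal(unname(cx[, "a"]), c(-1, 0, 1))
  expect_equal(unname(cx[, "b"]), c(-1, 0, 1)) # mean 1 imputed, then centred
  expect_equal(attr(cx, "column_means"), c(a = 1, b = 1))
  expect_error(center_impute(cbind(a = c(NA_real_, NA_real_))), "missing")
})

test_that("centred columns sum to zero on random data", {
  spec <- two_breed_spec(n_per_breed = 20L, n_snps = 150L, seed = 23L,
                         missing_rate = 0.08)
  gm <- filter_missing(simulate_dataset(spec)$genotypes)
  cx <- center_impute(gm)
  expect_lt(max(abs(colSums(cx))) / nrow(cx), 1e-10)
})

test_that("the encode-filter-centre pipeline commutes with sample reordering", {
  spec <- two_breed_spec(n_per_breed = 12L, n_snps = 80L, seed = 29L,
                         missing_rate = 0.1)
  sim <- simulate_dataset(spec)
  perm <- sample(length(sim$raw$sample_ids))
  raw_p <- raw_genotype_table(
    sample_ids = sim$raw$sample_ids[perm],
    family_ids = sim$raw$family_ids[perm],
    snp_ids = sim$raw$snp_ids,
    a1 = sim$raw$a1[perm, , drop = FALSE],
    a2 = sim$raw$a2[perm, , drop = FALSE],
    chrom = sim$raw$chrom, pos = sim$raw$pos
  )
  c1 <- center_impute(filter_missing(encode(sim$raw, sim$truth$labels)))
  c2 <- center_impute(filter_missing(encode(raw_p, sim$truth$labels)))
  expect_equal(c2, c1[rownames(c2), , drop = FALSE],
               ignore_attr = TRUE)
})
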