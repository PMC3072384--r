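test_that("spec validation names the offending field", {
  expect_error(breed_tree_spec(c("A", "A"), 0.1, 5, 10), "nodes")
  expect_error(breed_tree_spec(c("A", "B"), 1.2, 5, 10), "branch_fst")
  expect_error(breed_tree_spec(c("A", "B"), 0.1, 0, 10), "n_per_breed")
  expect_error(breed_tree_spec(c("A", "B"), 0.1, 5, 10, missing_rate = 1),
               "missing_rate")
  expect_error(breed_tree_spec(c("A", "B"), 0.1, 5, 10,
                               redundancy_flip_prob = 0.5),
               "redundancy_flip_prob")
  expect_error(breed_tree_spec(c("A", "B"), 0.1, 5, 10,
                               ancestral_freq_range = c(0.9, 0.1)),
               "ancestral_freq_range")
})

test_that("identical seeds give bit-identical datasets", {
  spec <- two_breed_spec(seed = 7L, n_per_breed = 10L, n_snps = 200L,
                         missing_rate = 0.05, redundancy_factor = 2L)
  s1 <- simulate_dataset(spec)
  s2 <- simulate_dataset(spec)
  expect_identical(s1$genotypes$values, s2$genotypes$values)
  expect_identical(s1$raw$a1, s2$raw$a1)
  expect_identical(s1$truth, s2$truth)
})

test_that("no-drift limit yields near-zero Weir-Cockerham FST", {
  spec <- two_breed_spec(fst = 1e-6, n_per_breed = 50L, n_snps = 1000L,
                         seed = 3L)
  sim <- simulate_dataset(spec)
  expect_lt(abs(wc_fst(sim$genotypes)), 0.01)
  # breed frequencies essentially equal the ancestral ones
  expect_lt(max(abs(sim$truth$breed_freq[1, ] - sim$truth$ancestral_freq)),
            0.01)
})

test_that("realised FST matches the Balding-Nichols drift parameter", {
  spec <- two_breed_spec(fst = 0.15, n_per_breed = 50L, n_snps = 2000L,
                         seed = 11L)
  sim <- simulate_dataset(spec)
  est <- wc_fst(sim$genotypes)
  expect_gt(est, 0.10)
  expect_lt(est, 0.20)
})

test_that("across-breed frequency variance follows F p (1 - p)", {
  # E[(p_breed - p_anc)^2] = F p_anc (1 - p_anc); mild F and an interior
  # ancestral range keep the clamping at 0.01/0.99 irrelevant
  fst <- 0.02
  spec <- breed_tree_spec(c("A", "B"), branch_fst = fst, n_per_breed = 2L,
                          n_snps = 3000L,
                          ancestral_freq_range = c(0.4, 0.6), seed = 5L)
  sim <- simulate_dataset(spec)
  pa <- sim$truth$ancestral_freq
  ratio <- sweep(sim$truth$breed_freq, 2, pa)^2 / rep(pa * (1 - pa), each = 2)
  se <- fst * sqrt(2 / length(ratio)) # relative sd of a chi-square(1) is sqrt(2)
  expect_lt(abs(mean(ratio) - fst), 3 * se)
})

test_that("missing-call fraction matches the configured rate", {
  rate <- 0.08
  spec <- two_breed_spec(n_per_breed = 25L, n_snps = 800L, seed = 9L,
                         missing_rate = rate)
  sim <- simulate_dataset(spec)
  n_calls <- length(sim$genotypes$values)
  se <- sqrt(rate * (1 - rate) / n_calls)
  expect_lt(abs(mean(is.na(sim$genotypes$values)) - rate), 3 * se)
})

test_that("exact duplicates are identical columns and recorded in truth", {
  spec <- two_breed_spec(n_per_breed = 10L, n_snps = 100L, seed = 13L,
                         redundancy_factor = 3L, redundancy_fraction = 0.3,
                         redundancy_flip_prob = 0)
  sim <- simulate_dataset(spec)
  groups <- split(names(sim$truth$dup_group), sim$truth$dup_group)
  multi <- groups[lengths(groups) > 1]
  expect_length(multi, 30L)
  expect_true(all(lengths(multi) == 3L))
  for (g in multi[1:5]) {
    base <- sim$raw$a1[, g[1]]
    for (dup in g[-1]) expect_identical(sim$raw$a1[, dup], base)
  }
})

test_that("fixtures round-trip through PED/MAP losslessly", {
  spec <- breed_tree_spec(
    nodes = list(g1 = c("A", "B"), g2 = "C"), branch_fst = c(0.2, 0.1),
    n_per_breed = 6L, n_snps = 50L, missing_rate = 0.1, seed = 21L
  )
  sim <- simulate_dataset(spec)
  dir <- withr::local_tempdir()
  paths <- export_fixture(sim, dir)
  back <- read_genotypes(paths[["ped"]], paths[["map"]])
  expect_identical(back$a1, sim$raw$a1)
  expect_identical(back$a2, sim$raw$a2)
  expect_identical(back$sample_ids, sim$raw$sample_ids)
  expect_identical(back$snp_ids, sim$raw$snp_ids)
  labs <- read_labels(paths[["labels"]], back$sample_ids)
  expect_identical(labs, sim$truth$labels)
  # re-encoding reproduces the genotype matrix, missing mask included
  gm2 <- encode(back, labs)
  expect_identical(gm2$values, sim$genotypes$values)
})

test_that("exported files are byte-stable for a fixed seed", {
  spec <- breed_tree_spec(
    nodes = list(g1 = c("A", "B"), g2 = "C"), branch_fst = c(0.2, 0.1),
    n_per_breed = 5L, n_snps = 40L, missing_rate = 0.05, seed = 31L
  )
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- export_fixture(simulate_dataset(spec), d1)
  p2 <- export_fixture(simulate_dataset(spec), d2)
  for (f in names(p1)) {
    expect_identical(unname(tools::md5sum(p1[[f]])),
                     unname(tools::md5sum(p2[[f]])), label = f)
  }
})

test_that("a zero-SNP table writes and re-reads as valid empty files", {
  raw <- raw_genotype_table(
    sample_ids = c("S1", "S2"), family_ids = c("F", "F"),
    snp_ids = character(),
    a1 = matrix("0", 2, 0), a2 = matrix("0", 2, 0),
    chrom = character(), pos = integer()
  )
  dir <- withr::local_tempdir()
  write_ped(raw, file.path(dir, "e.ped"), file.path(dir, "e.map"))
  back <- read_genotypes(file.path(dir, "e.ped"), file.path(dir, "e.map"))
  expect_identical(back$sample_ids, raw$sample_ids)
  expect_length(back$snp_ids, 0L)
})

test_that("wc_fst reproduces an independently computed reference value", {
  # frozen value from an independent implementation of the Weir-Cockerham
  # (1984) variance components on this fixture
  vals <- rbind(
    cbind(c(0, 0, 1, 2, 1), c(1, 1, 0, 0, 1)),
    cbind(c(2, 2, 1, 1, 2), c(0, 1, 1, 0, 0))
  )
  colnames(vals) <- c("snp1", "snp2")
  pops <- rep(c("A", "B"), each = 5)
  expect_equal(wc_fst(vals, pops), 0.09574468085106384, tolerance = 1e-12)
})
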