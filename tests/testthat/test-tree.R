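coords_1d <- function(x, ids) {
  matrix(x, ncol = 1, dimnames = list(ids, NULL))
}

test_that("separable breeds cluster cleanly with purity one", {
  set.seed(103)
  coords <- coords_1d(c(rnorm(10, -5, 0.3), rnorm(10, 5, 0.3)),
                      sprintf("i%02d", 1:20))
  labels <- rep(c("A", "B"), each = 10)
  cl <- cluster_breeds_at_node(coords, labels, 2)
  expect_setequal(vapply(cl$partition, paste, "", collapse = "+"), c("A", "B"))
  expect_equal(unname(cl$purity), c(1, 1))
})

test_that("identical coordinates are a degenerate clustering input", {
  coords <- coords_1d(rep(1, 10), sprintf("i%02d", 1:10))
  expect_error(cluster_breeds_at_node(coords, rep(c("A", "B"), 5), 2),
               "degenerate")
})

test_that("a close breed pair groups together against a distant outgroup", {
  spec <- breed_tree_spec(
    nodes = list(P = c("A", "B"), O = "C"),
    branch_fst = c(0.2, 0.02), # pair diverged little, outgroup a lot
    n_per_breed = 20L, n_snps = 600L, seed = 107L
  )
  gm <- filter_missing(simulate_dataset(spec)$genotypes)
  x <- center_impute(gm)
  fit <- fit_pca(x, 2)
  labels <- unname(gm$labels[rownames(x)])
  set.seed(1)
  cl <- cluster_breeds_at_node(fit$coords, labels, 2)
  parts <- vapply(cl$partition, paste, "", collapse = "+")
  expect_true("A+B" %in% parts)
  expect_true("C" %in% parts)
})

test_that("two breeds build a root with two leaf children", {
  spec <- two_breed_spec(fst = 0.3, n_per_breed = 10L, n_snps = 150L,
                         seed = 109L)
  gm <- filter_missing(simulate_dataset(spec)$genotypes)
  tree <- build_tree(gm, panels = FALSE, seed = 1)
  expect_identical(names(tree$root$children), c("A", "B"))
  expect_true(all(vapply(tree$root$children, `[[`, TRUE, "is_leaf")))
})

test_that("the reference bovine topology has 19 leaves and the named nodes", {
  topo <- bovine_tree_topology()
  leaves <- breedtrace:::tree_leaves(topo)
  expect_length(leaves, 19L)
  expect_identical(anyDuplicated(leaves), 0L)
  settings <- bovine_node_settings("reference")
  expect_setequal(
    names(settings$k),
    c("World", "BosTaurus", "BosIndicus", "Hybrids", "EuropeanTaurine",
      "SevenTaurine", "AngusRedAngus")
  )
  small <- bovine_node_settings("small")
  expect_identical(small$tier_sizes, c(P1 = 10L, P2 = 25L, P3 = 50L))
})

test_that("an explicit topology is reproduced with per-node settings applied", {
  set.seed(5)
  topo <- bovine_tree_topology()
  spec <- breed_tree_spec(
    nodes = topo, branch_fst = c(0.15, 0.08, 0.05, 0.05, 0.05),
    n_per_breed = 6L, n_snps = 1500L, seed = 113L
  )
  gm <- filter_missing(simulate_dataset(spec)$genotypes)
  settings <- bovine_node_settings("reference")
  tree <- build_tree(gm, topology = topo, k = settings$k,
                     p1_size = settings$p1_size, seed = 1,
                     root_name = "World")
  nodes <- breedtrace:::internal_nodes(tree)
  node_names <- vapply(nodes, `[[`, "", "name")
  expect_setequal(node_names, names(settings$k))
  for (nd in nodes) {
    expect_identical(nd$k, min(as.integer(settings$k[[nd$name]]),
                               length(nd$train_ids) - 1L))
    p1 <- as.integer(settings$p1_size[[nd$name]])
    expect_identical(nd$panels$tiers, c(P1 = p1, P2 = 2L * p1, P3 = 3L * p1))
  }
  # worked descent for an Angus individual follows the five-node path
  res <- classify_sample(tree, gm$values["Angus_001", ], mode = "full",
                         sample_id = "Angus_001", test_breed = "Angus")
  expect_identical(vapply(res$path, `[[`, "", "node"),
                   c("World", "BosTaurus", "EuropeanTaurine", "SevenTaurine",
                     "AngusRedAngus"))
  expect_identical(res$final, "Angus")
})

test_that("the planted two-level hierarchy is recovered by the auto builder", {
  sim <- simulate_dataset(two_level_spec(seed = 7L, n_per_breed = 20L,
                                         n_snps = 1200L))
  gm <- filter_missing(sim$genotypes)
  tree <- build_tree(gm, panels = FALSE, seed = 7)
  first <- lapply(tree$root$children, `[[`, "breeds")
  expect_setequal(vapply(first, paste, "", collapse = "+"),
                  c("B1+B2+B3", "B4+B5+B6"))
  # second level fully separates the breeds
  for (ch in tree$root$children) {
    expect_setequal(names(ch$children), ch$breeds)
  }
})

test_that("the 5-NN majority rule matches its fixtures", {
  train <- coords_1d(c(1, 1.1, 1.2, 3, 3.1, 9), sprintf("t%d", 1:6))
  # neighbours A,A,A,B,B -> A
  d <- knn_vote(1.5, train, c("A", "A", "A", "B", "B", "C"),
                train_breeds = c("A", "A", "A", "B", "B", "C"),
                test_breed = "A")
  expect_identical(d$predicted, "A")
  expect_identical(d$correct_neighbors, 3L)
  expect_true(all(diff(d$distances) >= 0))
  # no group reaches three votes -> unassigned
  d2 <- knn_vote(1.5, train, c("A", "A", "B", "B", "C", "C"))
  expect_identical(d2$predicted, "unassigned")
  # all five neighbours from the test breed -> maximal correct count
  train3 <- coords_1d(c(1, 1, 1, 1, 1, 50), sprintf("t%d", 1:6))
  d3 <- knn_vote(0, train3, rep("A", 6), rep("X", 6), "X")
  expect_identical(d3$correct_neighbors, 5L)
  # fewer than five training samples: all vote, majority is ceiling(m/2)
  train4 <- coords_1d(c(1, 2, 3), sprintf("t%d", 1:3))
  d4 <- knn_vote(0, train4, c("A", "A", "B"))
  expect_identical(d4$predicted, "A")
  expect_error(knn_vote(0, train4[0, , drop = FALSE], character()), "empty")
})

test_that("distance ties break deterministically by sample id", {
  train <- coords_1d(c(1, -1, 1, -1, 2, -2, 3), sprintf("t%d", 1:7))
  d <- knn_vote(0, train, rep("A", 7))
  expect_identical(d$neighbor_ids, c("t1", "t2", "t3", "t4", "t5"))
})

test_that("classification stops at the first unassigned node", {
  # hand-built one-level tree whose training cloud forces a 2/2/1 vote
  V <- matrix(c(1, 0), 2, 1, dimnames = list(c("s1", "s2"), NULL))
  coords <- coords_1d(c(9, 11, 8.8, 11.2, 7), sprintf("t%d", 1:5))
  basis <- breedtrace:::pc_basis(V, sigma = 1, column_means = c(0, 0), k = 1,
                                 snp_ids = c("s1", "s2"))
  breeds <- c("A", "A", "B", "B", "C")
  node <- list(
    name = "root", breeds = c("A", "B", "C"), is_leaf = FALSE, k = 1L,
    basis_full = basis, coords_full = coords,
    train_ids = rownames(coords), train_breeds = breeds,
    child_of = c(A = "A", B = "B", C = "C"),
    children = list(
      A = list(name = "A", breeds = "A", is_leaf = TRUE, children = NULL),
      B = list(name = "B", breeds = "B", is_leaf = TRUE, children = NULL),
      C = list(name = "C", breeds = "C", is_leaf = TRUE, children = NULL)
    )
  )
  tree <- structure(list(root = node, breeds = c("A", "B", "C")),
                    class = "breed_tree")
  res <- classify_sample(tree, c(s1 = 10, s2 = 0), mode = "full")
  expect_identical(res$final, "unassigned")
  expect_length(res$path, 1L)
})

test_that("a held-out individual descends to its own breed leaf", {
  sim <- simulate_dataset(breed_tree_spec(
    nodes = list(g1 = c("B1", "B2"), g2 = c("B3", "B4")),
    branch_fst = c(0.2, 0.2), n_per_breed = 12L, n_snps = 500L, seed = 127L
  ))
  gm <- filter_missing(sim$genotypes)
  hold <- "B3_001"
  train_gm <- gm
  keep <- setdiff(rownames(gm$values), hold)
  train_gm$values <- gm$values[keep, ]
  train_gm$labels <- gm$labels[keep]
  tree <- build_tree(train_gm, p1_size = 10L, seed = 3)
  for (mode in c("full", "P1", "P3")) {
    res <- classify_sample(tree, gm$values[hold, ], mode = mode,
                           test_breed = "B3")
    expect_identical(res$final, "B3", label = mode)
  }
})
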