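#' Group breeds into clusters along significant PCs
#'
#' Runs k-means (multiple restarts, best within-cluster sum of squares) on
#' the node's significant-PC coordinates of the training individuals, then
#' assigns every breed — breeds are atomic and never split — to the cluster
#' containing the plurality of its members (ties to the lower cluster
#' index). Clusters to which no breed is assigned are dropped.
#'
#' @param coords Training coordinates (samples x k) from [fit_pca()].
#' @param labels Breed label per row of `coords`.
#' @param n_clusters Number of k-means clusters, between 2 and the number of
#'   breeds.
#' @param nstart k-means restarts (default 20). Seed the RNG beforehand for
#'   reproducible restarts.
#' @return List with `partition` (list of character vectors of breed names,
#'   one per surviving cluster) and `purity` (named per-breed fraction of
#'   its individuals inside its assigned cluster).
#' @export
cluster_breeds_at_node <- function(coords, labels, n_clusters, nstart = 20L) {
  stopifnot(is.matrix(coords), length(labels) == nrow(coords))
  breeds <- sort(unique(labels))
  if (length(breeds) < 2L) stop("need at least two breeds", call. = FALSE)
  if (n_clusters < 2L || n_clusters > length(breeds)) {
    stop("n_clusters must lie between 2 and the number of breeds", call. = FALSE)
  }
  n_distinct <- nrow(unique(coords))
  if (n_distinct < n_clusters) {
    stop("degenerate coordinates: fewer distinct points than clusters",
         call. = FALSE)
  }
  km <- suppressWarnings(
    kmeans(coords, centers = n_clusters, nstart = nstart, iter.max = 100L)
  )
  cl_of_breed <- vapply(breeds, function(b) {
    counts <- tabulate(km$cluster[labels == b], nbins = n_clusters)
    which.max(counts) # ties -> lower cluster index
  }, integer(1))
  purity <- vapply(breeds, function(b) {
    counts <- tabulate(km$cluster[labels == b], nbins = n_clusters)
    max(counts) / sum(counts)
  }, numeric(1))
  partition <- lapply(
    sort(unique(cl_of_breed)),
    function(cl) sort(breeds[cl_of_breed == cl])
  )
  list(partition = partition, purity = purity)
}

#' Default number of breed clusters at a node
#'
#' Detects multi-scale structure among the breeds: an average-linkage
#' dendrogram is built on the breed centroids in the node's significant-PC
#' space, and if the largest ratio between successive merge heights is at
#' least `gap_ratio` the dendrogram is cut at that gap (giving the number of
#' clusters above it); otherwise there is no coarse grouping and every breed
#' becomes its own child.
#'
#' @inheritParams cluster_breeds_at_node
#' @param gap_ratio Minimum successive merge-height ratio that counts as a
#'   scale gap (default 1.5).
#' @return Integer number of clusters (equal to the number of breeds when no
#'   gap is found).
#' @export
auto_n_clusters <- function(coords, labels, gap_ratio = 1.5) {
  breeds <- sort(unique(labels))
  B <- length(breeds)
  if (B <= 2L) return(B)
  cent <- matrix(0, B, ncol(coords))
  for (i in seq_len(B)) {
    cent[i, ] <- colMeans(coords[labels == breeds[i], , drop = FALSE])
  }
  hc <- hclust(dist(cent), method = "average")
  h <- hc$height
  eps <- max(h, 1e-300) * 1e-12
  ratios <- (h[-1] + eps) / (h[-length(h)] + eps)
  j <- which.max(ratios)
  if (length(ratios) && ratios[j] >= gap_ratio) B - j else B
}

#' Reference decision-tree topology of the bovine study system
#'
#' The fixed breed hierarchy for the 19 worldwide cattle breeds (13 taurine,
#' 3 zebu, 3 taurine-zebu hybrid): the root separates *Bos indicus*,
#' *Bos taurus* and the hybrid breeds; *B. taurus* splits into the African
#' N'Dama and the European taurine breeds; the European taurine node isolates
#' Holstein, Hereford, Jersey, Brown Swiss and Romagnola from a
#' seven-taurine-breed group, which in turn isolates Guernsey, Limousin,
#' Charolais, Norwegian Red and Piedmontese from the Angus/Red Angus pair.
#'
#' @return Nested named list usable as the `topology` argument of
#'   [build_tree()] (19 leaves, 7 internal nodes including the root
#'   "World").
#' @export
bovine_tree_topology <- function() {
  list(
    BosIndicus = c("Brahman", "Gir", "Nelore"),
    BosTaurus = list(
      NDama = "NDama",
      EuropeanTaurine = list(
        Holstein = "Holstein", Hereford = "Hereford", Jersey = "Jersey",
        BrownSwiss = "BrownSwiss", Romagnola = "Romagnola",
        SevenTaurine = list(
          Guernsey = "Guernsey", Limousin = "Limousin",
          Charolais = "Charolais", NorwegianRed = "NorwegianRed",
          Piedmontese = "Piedmontese",
          AngusRedAngus = c("Angus", "RedAngus")
        )
      )
    ),
    Hybrids = c("Beefmaster", "SantaGertrudis", "Sheko")
  )
}

#' Reference per-node settings for the bovine decision tree
#'
#' Significant-PC counts and P1 panel sizes per internal node of
#' [bovine_tree_topology()] (P2/P3 are twice/three times P1). The `"small"`
#' preset uses tiers of 10/25/50 SNPs at every node instead.
#'
#' @param preset `"reference"` (per-node sizes) or `"small"` (10/25/50
#'   everywhere).
#' @return List with elements `k` (named integer vector per node) and either
#'   `p1_size` (named, `"reference"`) or `tier_sizes` (`"small"`).
#' @export
bovine_node_settings <- function(preset = c("reference", "small")) {
  preset <- match.arg(preset)
  k <- c(World = 2L, BosTaurus = 1L, BosIndicus = 3L, Hybrids = 3L,
         EuropeanTaurine = 4L, SevenTaurine = 4L, AngusRedAngus = 3L)
  if (preset == "reference") {
    list(k = k,
         p1_size = c(World = 100L, BosTaurus = 10L, BosIndicus = 50L,
                     Hybrids = 25L, EuropeanTaurine = 100L,
                     SevenTaurine = 150L, AngusRedAngus = 25L))
  } else {
    list(k = k, tier_sizes = c(P1 = 10L, P2 = 25L, P3 = 50L))
  }
}

# resolve a possibly per-node configuration value
resolve_node_cfg <- function(cfg, node_name) {
  if (is.null(cfg)) return(NULL)
  if (is.list(cfg) || (!is.null(names(cfg)) && all(nzchar(names(cfg))))) {
    if (node_name %in% names(cfg)) return(cfg[[node_name]])
    if (is.list(cfg)) return(NULL)
  }
  if (length(cfg) == 1L && is.null(names(cfg))) return(cfg)
  if (length(cfg) == 1L) return(NULL)
  cfg
}

#' Build the breed decision tree
#'
#' Recursively: fit PCA at the node (on all post-QC SNPs of the node's
#' training individuals), determine the number of significant components,
#' group the breeds into child clusters, build nested marker panels, and
#' recurse into every multi-breed child until each leaf holds one breed.
#' The topology can also be supplied explicitly (e.g.
#' [bovine_tree_topology()]), in which case only the per-node models and
#' panels are fitted.
#'
#' @param gm A QC'd `genotype_matrix` (see [filter_missing()]) with at least
#'   two breeds.
#' @param topology `"auto"` (recursive clustering) or a nested named list: a
#'   character element of length one is a leaf breed; a longer character
#'   vector is an internal node whose children are those breeds; a list is
#'   an internal node with explicit sub-structure.
#' @param k `"auto"` ([choose_num_pcs()] per node), a single integer, or a
#'   named vector/list of per-node values.
#' @param k_candidates Candidates for automatic `k` (default `1:6`).
#' @param n_clusters `"auto"` ([auto_n_clusters()] per node) or a fixed
#'   integer (capped at the node's breed count).
#' @param n_top Candidate pool size per node; default
#'   `min(2000, floor(n_snps / 3))`, raised to the largest tier if needed.
#' @param p1_size Smallest panel-tier size (single value or named per node);
#'   default 50, giving P1/P2/P3 = 50/100/150.
#' @param tier_sizes Optional explicit tier sizes (length-3 vector, or named
#'   list of vectors per node); overrides `p1_size`.
#' @param panels If `FALSE`, skip panel selection (topology and full-SNP
#'   bases only).
#' @param gap_ratio Scale-gap threshold for [auto_n_clusters()].
#' @param seed Seed for the k-means restarts (all other steps are
#'   deterministic).
#' @param root_name Name of the root node.
#' @return Object of class `breed_tree`.
#' @export
build_tree <- function(gm, topology = "auto", k = "auto", k_candidates = 1:6,
                       n_clusters = "auto", n_top = NULL, p1_size = 50L,
                       tier_sizes = NULL, panels = TRUE, gap_ratio = 1.5,
                       seed = 1L, root_name = "root") {
  stopifnot(inherits(gm, "genotype_matrix"))
  breeds <- sort(unique(unname(gm$labels)))
  if (length(breeds) < 2L) stop("need >= 2 breeds to build a tree", call. = FALSE)
  m <- ncol(gm$values)
  cfg <- list(
    topology = topology, k = k, k_candidates = k_candidates,
    n_clusters = n_clusters,
    n_top = n_top %||% min(2000L, max(floor(m / 3), 1L)),
    p1_size = p1_size, tier_sizes = tier_sizes, panels = panels,
    gap_ratio = gap_ratio, seed = seed
  )
  set.seed(seed)
  topo <- if (identical(topology, "auto")) NULL else topology
  if (!is.null(topo)) {
    topo_breeds <- sort(tree_leaves(topo))
    if (!identical(topo_breeds, breeds)) {
      stop("topology breeds do not match the data's breeds", call. = FALSE)
    }
  }
  root <- build_node(gm, breeds, root_name, topo, cfg)
  structure(
    list(root = root, breeds = breeds, labels = gm$labels,
         snp_ids = colnames(gm$values), config = cfg),
    class = "breed_tree"
  )
}

build_node <- function(gm, breeds, name, topo, cfg) {
  breeds <- sort(breeds)
  if (length(breeds) == 1L) {
    return(list(name = breeds, breeds = breeds, is_leaf = TRUE,
                children = NULL))
  }
  samples <- names(gm$labels)[gm$labels %in% breeds]
  X <- center_impute(gm$values[samples, , drop = FALSE])
  blab <- unname(gm$labels[samples])

  k_cfg <- resolve_node_cfg(if (identical(cfg$k, "auto")) NULL else cfg$k, name)
  k <- if (is.null(k_cfg)) {
    choose_num_pcs(X, blab, cfg$k_candidates)
  } else {
    as.integer(k_cfg)
  }
  k <- min(k, length(samples) - 1L, ncol(X))
  fit <- fit_pca(X, k)

  # clustering inspects the between-breed geometry, which spans at most
  # B - 1 dimensions: a node k chosen for classification can be smaller and
  # would collapse distinct breeds onto one axis
  k_clu <- min(max(k, length(breeds) - 1L), length(samples) - 1L, ncol(X), 6L)
  clu_coords <- if (k_clu == k) fit$coords else fit_pca(X, k_clu)$coords

  purity <- NULL
  if (!is.null(topo)) {
    groups <- lapply(topo, tree_leaves)
    child_names <- names(topo) %||%
      vapply(groups, function(g) paste(sort(g), collapse = "+"), "")
    child_topo <- lapply(seq_along(topo), function(i) {
      el <- topo[[i]]
      if (is.list(el)) el
      else if (length(el) > 1L) as.list(setNames(el, el))
      else NULL
    })
  } else {
    nc <- if (identical(cfg$n_clusters, "auto")) {
      auto_n_clusters(clu_coords, blab, cfg$gap_ratio)
    } else {
      min(as.integer(cfg$n_clusters), length(breeds))
    }
    if (nc >= length(breeds)) {
      groups <- as.list(breeds)
    } else {
      cl <- cluster_breeds_at_node(clu_coords, blab, nc)
      groups <- cl$partition
      purity <- cl$purity
      if (length(groups) < 2L) groups <- as.list(breeds) # plurality collapse
    }
    child_names <- vapply(
      groups,
      function(g) if (length(g) == 1L) g else paste(sort(g), collapse = "+"),
      ""
    )
    child_topo <- vector("list", length(groups))
  }
  names(groups) <- child_names
  child_of <- setNames(
    rep(child_names, lengths(groups)), unlist(groups, use.names = FALSE)
  )

  # an auto-chosen k is floored at (children - 1): separating c groups in
  # general position needs at least c - 1 axes, and a smaller k starves the
  # panel leverage scores of the discriminative directions
  if (is.null(k_cfg)) {
    k_floor <- min(max(k, length(groups) - 1L),
                   length(samples) - 1L, ncol(X))
    if (k_floor != k) {
      k <- k_floor
      fit <- fit_pca(X, k)
    }
  }

  node <- list(
    name = name, breeds = breeds, is_leaf = FALSE,
    k = k, basis_full = fit$basis, coords_full = fit$coords,
    train_ids = samples, train_breeds = blab, child_of = child_of,
    purity = purity,
    n_top = min(max(cfg$n_top, 1L), ncol(X)),
    tier_sizes = node_tier_sizes(cfg, name)
  )

  if (isTRUE(cfg$panels)) {
    node$n_top <- min(max(node$n_top, max(node$tier_sizes)), ncol(X))
    node$panels <- build_panels(X, fit$basis, n_top = node$n_top,
                                tier_sizes = node$tier_sizes, node = name)
    cand <- top_candidates(pcaim_scores(fit$basis), node$n_top)
    node$cand_ids <- cand
    fit_c <- refit_on_subset(X, cand, k)
    node$cand_basis <- fit_c$basis
    node$cand_coords <- fit_c$coords
    node$panel_bases <- list()
    node$panel_coords <- list()
    for (t in names(node$tier_sizes)) {
      ids <- node$panels$snp_ids[seq_len(node$tier_sizes[[t]])]
      fit_t <- refit_on_subset(X, ids, k)
      node$panel_bases[[t]] <- fit_t$basis
      node$panel_coords[[t]] <- fit_t$coords
    }
  }

  node$children <- setNames(vector("list", length(groups)), child_names)
  for (i in seq_along(groups)) {
    node$children[[i]] <- build_node(gm, groups[[i]], child_names[i],
                                     child_topo[[i]], cfg)
  }
  node
}

node_tier_sizes <- function(cfg, name) {
  ts <- resolve_node_cfg(cfg$tier_sizes, name)
  if (!is.null(ts)) {
    ts <- as.integer(ts)
    if (is.null(names(ts)) || !all(nzchar(names(ts)))) {
      names(ts) <- paste0("P", seq_along(ts))
    }
    return(ts)
  }
  p1 <- as.integer(resolve_node_cfg(cfg$p1_size, name) %||% 50L)
  c(P1 = p1, P2 = 2L * p1, P3 = 3L * p1)
}

# refit PCA on a column subset of an already-centred matrix
refit_on_subset <- function(X, ids, k) {
  Xs <- X[, ids, drop = FALSE]
  cm <- attr(X, "column_means")[ids]
  attr(Xs, "column_means") <- cm
  k_eff <- min(k, nrow(Xs) - 1L, ncol(Xs))
  fit_pca(Xs, k_eff, column_means = cm)
}

#' @export
print.breed_tree <- function(x, ...) {
  n_internal <- length(internal_nodes(x))
  cat(sprintf("breed_tree: %d breeds, %d internal nodes, root '%s'\n",
              length(x$breeds), n_internal, x$root$name))
  print_node <- function(node, indent) {
    tag <- if (node$is_leaf) "" else sprintf(" [k=%d]", node$k)
    cat(strrep("  ", indent), "- ", node$name, tag, "\n", sep = "")
    for (ch in node$children) print_node(ch, indent + 1L)
  }
  print_node(x$root, 0L)
  invisible(x)
}

# flat list of all internal nodes (root first, depth-first)
internal_nodes <- function(tree) {
  out <- list()
  walk <- function(node) {
    if (node$is_leaf) return(invisible())
    out[[length(out) + 1L]] <<- node
    for (ch in node$children) walk(ch)
  }
  walk(tree$root)
  out
}

# root-to-leaf sequence of internal nodes (with the correct child at each)
# for a given breed
path_for_breed <- function(tree, breed) {
  path <- list()
  node <- tree$root
  while (!node$is_leaf) {
    child <- node$child_of[[breed]]
    path[[length(path) + 1L]] <- list(node = node, child = child)
    node <- node$children[[child]]
  }
  path
}

#' Five-nearest-neighbour vote at one node
#'
#' Finds the test sample's nearest training neighbours by Euclidean distance
#' in the node's significant-PC subspace (distance ties broken by sample id)
#' and assigns the sample to the child group holding a majority — at least 3
#' of 5 — of them, or `"unassigned"` if no group reaches the majority. With
#' fewer than `k_nn` training samples all of them vote and the majority is
#' `ceiling(m/2)`. Also records how many neighbours belong to the test
#' sample's own reference breed (`NA` when the breed is unknown).
#'
#' @param test_coords Numeric k-vector of the test sample's coordinates.
#' @param train_coords Training coordinate matrix (rownames = sample ids).
#' @param train_children Child-group label per training sample.
#' @param train_breeds Breed per training sample (for the correct-neighbour
#'   count).
#' @param test_breed Reference breed of the test sample, or `NA`.
#' @param k_nn Number of neighbours (default 5).
#' @return Object of class `node_decision`: `predicted` (child name or
#'   `"unassigned"`), `neighbor_ids`, `distances` (non-decreasing),
#'   `correct_neighbors`.
#' @export
knn_vote <- function(test_coords, train_coords, train_children,
                     train_breeds = NULL, test_breed = NA_character_,
                     k_nn = 5L) {
  m <- nrow(train_coords)
  if (is.null(m) || m == 0L) stop("empty training set", call. = FALSE)
  stopifnot(length(train_children) == m)
  ids <- rownames(train_coords) %||% sprintf("s%06d", seq_len(m))
  d <- sqrt(colSums((t(train_coords) - as.numeric(test_coords))^2))
  ord <- order(d, ids)
  kk <- min(k_nn, m)
  nn <- ord[seq_len(kk)]
  maj <- ceiling(kk / 2)
  votes <- table(train_children[nn])
  top <- max(votes)
  predicted <- if (top >= maj) {
    winners <- names(votes)[votes == top]
    sort(winners)[1] # deterministic on exact vote ties
  } else {
    "unassigned"
  }
  correct <- if (is.null(train_breeds) || is.na(test_breed)) {
    NA_integer_
  } else {
    sum(train_breeds[nn] == test_breed)
  }
  structure(
    list(node = NA_character_, predicted = predicted,
         neighbor_ids = ids[nn], distances = d[nn],
         correct_neighbors = correct),
    class = "node_decision"
  )
}

#' Classify one sample by descending the decision tree
#'
#' Starting at the root, the sample is restricted to the node's SNP set for
#' the chosen mode (all SNPs, the candidate set, or a panel tier), projected
#' onto the node's matching PC basis, and voted on by its five nearest
#' training neighbours; the walk descends into the predicted child and stops
#' at a leaf (the predicted breed) or at the first `"unassigned"` decision.
#'
#' @param tree A fitted [build_tree()].
#' @param values Named numeric vector (or 1-row matrix) of minor-allele
#'   counts covering the tree's SNPs; `NA` = missing call.
#' @param mode `"full"`, `"candidates"`, or a panel tier (`"P1"`, `"P2"`,
#'   `"P3"`).
#' @param k_nn Neighbours per vote.
#' @param sample_id,test_breed Optional identifiers carried into the result
#'   (`test_breed` enables the correct-neighbour count).
#' @return Object of class `classification_result`: `sample_id`, `path`
#'   (list of `node_decision`s, root first), `final` (breed or
#'   `"unassigned"`).
#' @export
classify_sample <- function(tree, values, mode = "P3", k_nn = 5L,
                            sample_id = NA_character_,
                            test_breed = NA_character_) {
  stopifnot(inherits(tree, "breed_tree"))
  node <- tree$root
  path <- list()
  repeat {
    mt <- node_mode_tables(node, mode)
    tc <- project_samples(mt$basis, values)[1L, ]
    dec <- knn_vote(tc, mt$coords, node$child_of[node$train_breeds],
                    node$train_breeds, test_breed, k_nn)
    dec$node <- node$name
    path[[length(path) + 1L]] <- dec
    if (dec$predicted == "unassigned") {
      return(structure(list(sample_id = sample_id, path = path,
                            final = "unassigned"),
                       class = "classification_result"))
    }
    node <- node$children[[dec$predicted]]
    if (node$is_leaf) {
      return(structure(list(sample_id = sample_id, path = path,
                            final = node$name),
                       class = "classification_result"))
    }
  }
}

node_mode_tables <- function(node, mode) {
  if (mode == "full") {
    list(basis = node$basis_full, coords = node$coords_full)
  } else if (mode == "candidates") {
    if (is.null(node$cand_basis)) {
      stop("tree was built without panels; candidate mode unavailable",
           call. = FALSE)
    }
    list(basis = node$cand_basis, coords = node$cand_coords)
  } else if (mode %in% names(node$panel_bases %||% list())) {
    list(basis = node$panel_bases[[mode]], coords = node$panel_coords[[mode]])
  } else {
    stop(sprintf("mode '%s' not available at node '%s'", mode, node$name),
         call. = FALSE)
  }
}

#' @export
print.classification_result <- function(x, ...) {
  steps <- vapply(x$path, function(d) sprintf("%s -> %s", d$node, d$predicted), "")
  cat(sprintf("classification_result%s: final = %s\n",
              if (is.na(x$sample_id)) "" else paste0(" [", x$sample_id, "]"),
              x$final))
  cat(paste0("  ", steps, collapse = "\n"), "\n")
  invisible(x)
}
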