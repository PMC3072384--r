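#' Complete leave-one-out cross-validation of the breed-tracing pipeline
#'
#' Each sample in turn is held out and every internal node on its
#' root-to-leaf reference path is refitted on the remaining samples with the
#' tree topology held fixed: PCA, candidate ranking and redundancy-removed
#' panels are all re-derived from the training set only, so the held-out
#' individual never influences the markers that classify it. The held-out
#' sample is then assigned at each path node by the five-nearest-neighbour
#' vote in every requested mode, and per-node / per-breed statistics are
#' accumulated: a node decision is correct iff the predicted child contains
#' the sample's reference breed, and an `"unassigned"` decision counts as
#' incorrect.
#'
#' @param gm QC'd `genotype_matrix` (every breed needs at least two
#'   individuals).
#' @param tree Fitted [build_tree()] on the same data (only its topology and
#'   per-node settings are reused; all models are refit per fold).
#' @param modes Subset of `c("full", "candidates", "P1", "P2", "P3")`.
#' @param k_nn Neighbours per vote (default 5).
#' @param nodes Optional character vector of node names to evaluate (default
#'   all nodes on each sample's path); restricting to the root makes
#'   root-level robustness sweeps cheap.
#' @param verbose Print fold progress.
#' @return Object of class `eval_report`: `records` (one row per sample x
#'   node x mode), `per_node` (classification accuracy `accuracy` in
#'   percent, `avg_correct_neighbors` out of `k_nn`, `n_unassigned`), and
#'   `per_breed` (Table-style per-breed path statistics).
#' @export
loocv <- function(gm, tree, modes = c("full", "P1", "P2", "P3"), k_nn = 5L,
                  nodes = NULL, verbose = FALSE) {
  stopifnot(inherits(gm, "genotype_matrix"), inherits(tree, "breed_tree"))
  allowed <- c("full", "candidates", "P1", "P2", "P3")
  bad <- setdiff(modes, allowed)
  if (length(bad)) stop("unknown modes: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  counts <- table(gm$labels)
  if (any(counts < 2L)) {
    stop("every breed needs >= 2 individuals for leave-one-out; offending: ",
         paste(names(counts)[counts < 2L], collapse = ", "), call. = FALSE)
  }
  tier_modes <- intersect(modes, c("P1", "P2", "P3"))
  need_cand <- length(tier_modes) > 0L || "candidates" %in% modes

  paths <- lapply(tree$breeds, function(b) path_for_breed(tree, b))
  names(paths) <- tree$breeds

  sample_ids <- rownames(gm$values)
  rec <- list(sample = character(), breed = character(), node = character(),
              mode = character(), correct = logical(), unassigned = logical(),
              correct_neighbors = integer())
  add <- function(sample, breed, node, mode, dec, correct_child) {
    n <- length(rec$sample) + 1L
    rec$sample[n] <<- sample
    rec$breed[n] <<- breed
    rec$node[n] <<- node
    rec$mode[n] <<- mode
    rec$correct[n] <<- identical(dec$predicted, correct_child)
    rec$unassigned[n] <<- identical(dec$predicted, "unassigned")
    rec$correct_neighbors[n] <<- dec$correct_neighbors
  }

  for (f in seq_along(sample_ids)) {
    sid <- sample_ids[f]
    b <- unname(gm$labels[sid])
    test_vals <- gm$values[sid, ]
    for (step in paths[[b]]) {
      node <- step$node
      if (!is.null(nodes) && !(node$name %in% nodes)) next
      train <- setdiff(node$train_ids, sid)
      Xt <- center_impute(gm$values[train, , drop = FALSE])
      kk <- min(node$k, length(train) - 1L, ncol(Xt))
      fit <- fit_pca(Xt, kk)
      train_breeds <- unname(gm$labels[train])
      train_children <- unname(node$child_of[train_breeds])
      correct_child <- node$child_of[[b]]

      mode_fits <- list(full = fit)
      if (need_cand) {
        n_top <- min(node$n_top, ncol(Xt))
        cand <- top_candidates(pcaim_scores(fit$basis), n_top)
        if ("candidates" %in% modes) {
          mode_fits$candidates <- refit_on_subset(Xt, cand, kk)
        }
        if (length(tier_modes)) {
          cmax <- max(node$tier_sizes[tier_modes])
          sel <- cssp_select(Xt[, cand, drop = FALSE],
                             k = min(kk, length(cand)), c = cmax)
          for (t in tier_modes) {
            mode_fits[[t]] <- refit_on_subset(
              Xt, sel[seq_len(node$tier_sizes[[t]])], kk
            )
          }
        }
      }
      for (mode in modes) {
        mf <- mode_fits[[mode]]
        tc <- project_samples(mf$basis, test_vals)[1L, ]
        dec <- knn_vote(tc, mf$coords, train_children, train_breeds, b, k_nn)
        add(sid, b, node$name, mode, dec, correct_child)
      }
    }
    if (verbose && f %% 50L == 0L) {
      message(sprintf("loocv: %d/%d folds", f, length(sample_ids)))
    }
  }

  records <- data.frame(rec, stringsAsFactors = FALSE)
  node_order <- vapply(internal_nodes(tree), `[[`, "", "name")
  per_node <- summarise_records(records, c("node", "mode"), node_order, modes)
  per_breed <- summarise_records(records, c("breed", "node", "mode"),
                                 node_order, modes)
  structure(
    list(records = records, per_node = per_node, per_breed = per_breed,
         modes = modes, k_nn = k_nn),
    class = "eval_report"
  )
}

summarise_records <- function(records, by, node_order, mode_order) {
  if (nrow(records) == 0L) {
    return(data.frame())
  }
  key <- interaction(records[by], drop = TRUE, lex.order = TRUE)
  agg <- do.call(rbind, lapply(split(records, key), function(g) {
    out <- g[1L, by, drop = FALSE]
    out$n <- nrow(g)
    out$n_correct <- sum(g$correct)
    out$accuracy <- 100 * mean(g$correct)
    out$avg_correct_neighbors <- mean(g$correct_neighbors)
    out$n_unassigned <- sum(g$unassigned)
    out
  }))
  agg <- agg[order(match(agg$node, node_order),
                   if ("breed" %in% by) agg$breed else agg$node,
                   match(agg$mode, mode_order)), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report: %d samples, modes %s, k_nn = %d\n",
              length(unique(x$records$sample)),
              paste(x$modes, collapse = "/"), x$k_nn))
  print(x$per_node, row.names = FALSE)
  invisible(x)
}

#' Root-node accuracy as the neighbour count varies
#'
#' Repeats the leave-one-out experiment at the root node in full-SNP mode
#' for several values of the k-NN neighbour count, refitting the PCA once
#' per fold and voting at every `k_nn` value. Used to check that the
#' majority-vote classifier is insensitive to the exact neighbour count.
#'
#' @param gm QC'd `genotype_matrix`.
#' @param tree Fitted [build_tree()].
#' @param k_nn_values Neighbour counts to sweep (default `c(3, 5, 7, 9, 11)`).
#' @return Named numeric vector of root-node classification accuracies (in
#'   percent), one per neighbour count.
#' @export
knn_sweep <- function(gm, tree, k_nn_values = c(3L, 5L, 7L, 9L, 11L)) {
  stopifnot(inherits(gm, "genotype_matrix"), inherits(tree, "breed_tree"))
  node <- tree$root
  sample_ids <- node$train_ids
  correct <- matrix(FALSE, length(sample_ids), length(k_nn_values))
  for (f in seq_along(sample_ids)) {
    sid <- sample_ids[f]
    b <- unname(gm$labels[sid])
    train <- setdiff(node$train_ids, sid)
    Xt <- center_impute(gm$values[train, , drop = FALSE])
    kk <- min(node$k, length(train) - 1L, ncol(Xt))
    fit <- fit_pca(Xt, kk)
    tc <- project_samples(fit$basis, gm$values[sid, ])[1L, ]
    train_children <- unname(node$child_of[unname(gm$labels[train])])
    for (j in seq_along(k_nn_values)) {
      dec <- knn_vote(tc, fit$coords, train_children, k_nn = k_nn_values[j])
      correct[f, j] <- identical(dec$predicted, node$child_of[[b]])
    }
  }
  setNames(100 * colMeans(correct), paste0("k", k_nn_values))
}

#' Write evaluation report tables
#'
#' Emits the per-node summary and the per-breed path table as TSV (numbers
#' rounded to two decimals) and the full-precision report as JSON.
#'
#' @param report An [loocv()] report.
#' @param directory Output directory (created if needed).
#' @param prefix Basename prefix for the files.
#' @return Invisibly, named character vector of the written paths
#'   (`per_node`, `per_breed`, `json`).
#' @export
report_tables <- function(report, directory, prefix = "report") {
  stopifnot(inherits(report, "eval_report"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    per_node = file.path(directory, paste0(prefix, "_per_node.tsv")),
    per_breed = file.path(directory, paste0(prefix, "_per_breed.tsv")),
    json = file.path(directory, paste0(prefix, ".json"))
  )
  round2 <- function(df) {
    num <- vapply(df, is.numeric, logical(1)) &
      names(df) %in% c("accuracy", "avg_correct_neighbors")
    df[num] <- lapply(df[num], round, digits = 2)
    df
  }
  write.table(round2(report$per_node), paths[["per_node"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(round2(report$per_breed), paths[["per_breed"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(modes = report$modes, k_nn = report$k_nn,
         per_node = report$per_node, per_breed = report$per_breed),
    paths[["json"]], digits = NA, auto_unbox = TRUE, dataframe = "rows"
  )
  invisible(paths)
}
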