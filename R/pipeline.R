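#' Assemble a reproducible run configuration
#'
#' Exactly one input source must be given: either the PED/MAP/label file
#' triple, or a simulation spec. All randomness in a run (simulation,
#' k-means restarts) flows from the single `seed`.
#'
#' @param ped,map,labels Paths to the genotype and label files.
#' @param sim_spec A [breed_tree_spec()] to simulate the input instead.
#' @param topology,k,n_clusters,n_top,p1_size,tier_sizes,gap_ratio Passed to
#'   [build_tree()].
#' @param modes Evaluation modes for [loocv()].
#' @param k_nn Neighbours per vote.
#' @param max_missing_fraction Missingness threshold for [filter_missing()].
#' @param preset `NULL`, `"reference"` or `"small"`: bundles
#'   [bovine_tree_topology()] with [bovine_node_settings()] and root name
#'   `"World"`.
#' @param seed Integer run seed.
#' @param out_dir Output directory.
#' @param root_name Root node name.
#' @return Object of class `run_config`.
#' @export
run_config <- function(ped = NULL, map = NULL, labels = NULL, sim_spec = NULL,
                       topology = "auto", k = "auto", n_clusters = "auto",
                       n_top = NULL, p1_size = 50L, tier_sizes = NULL,
                       gap_ratio = 1.5, modes = c("full", "P1", "P2", "P3"),
                       k_nn = 5L, max_missing_fraction = 0.10, preset = NULL,
                       seed = 1L, out_dir = ".", root_name = "root") {
  have_files <- !is.null(ped) || !is.null(map) || !is.null(labels)
  have_sim <- !is.null(sim_spec)
  if (have_files == have_sim) {
    stop("give exactly one input source: ped/map/labels files, or sim_spec",
         call. = FALSE)
  }
  if (have_files && (is.null(ped) || is.null(map) || is.null(labels))) {
    stop("file input needs all of `ped`, `map` and `labels`", call. = FALSE)
  }
  if (have_sim && !inherits(sim_spec, "breed_tree_spec")) {
    stop("`sim_spec` must be a breed_tree_spec", call. = FALSE)
  }
  seed <- check_count(seed, "seed", min = 0L)
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("reference", "small"))
    settings <- bovine_node_settings(preset)
    topology <- bovine_tree_topology()
    root_name <- "World"
    k <- settings$k
    if (preset == "reference") p1_size <- settings$p1_size
    else tier_sizes <- settings$tier_sizes
  }
  structure(
    list(ped = ped, map = map, labels = labels, sim_spec = sim_spec,
         topology = topology, k = k, n_clusters = n_clusters, n_top = n_top,
         p1_size = p1_size, tier_sizes = tier_sizes, gap_ratio = gap_ratio,
         modes = modes, k_nn = as.integer(k_nn),
         max_missing_fraction = max_missing_fraction,
         seed = seed, out_dir = out_dir, root_name = root_name),
    class = "run_config"
  )
}

# load + QC the configured input; returns the filtered genotype_matrix
load_inputs <- function(config) {
  if (!is.null(config$sim_spec)) {
    sim <- simulate_dataset(config$sim_spec)
    gm <- sim$genotypes
  } else {
    raw <- read_genotypes(config$ped, config$map)
    labs <- read_labels(config$labels, raw$sample_ids)
    gm <- encode(raw, labs)
  }
  filter_missing(gm, config$max_missing_fraction)
}

#' Simulate a dataset and write fixture files
#'
#' @param config A [run_config()] with a `sim_spec`.
#' @return Invisibly, the named paths written by [export_fixture()].
#' @export
run_simulate <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$sim_spec)) {
    stop("run_simulate needs a config with `sim_spec`", call. = FALSE)
  }
  sim <- simulate_dataset(config$sim_spec)
  paths <- export_fixture(sim, config$out_dir)
  if (length(unique(sim$genotypes$labels)) >= 2L) {
    fst <- wc_fst(sim$genotypes)
    message(sprintf("simulated %d samples x %d SNPs; realised multi-SNP FST = %.4f",
                    nrow(sim$genotypes$values), ncol(sim$genotypes$values), fst))
  }
  invisible(paths)
}

#' Run QC, build the decision tree and write panels
#'
#' Stages: read or simulate genotypes, encode, missingness/monomorphism QC,
#' tree construction, panel selection. Writes `tree.yaml` (topology and
#' per-node settings), one panel TSV per internal node under `panels/`, and
#' `qc_summary.tsv`. Outputs are byte-stable for identical config + seed.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `tree`, `gm` (QC'd genotypes) and `paths`.
#' @export
run_build <- function(config) {
  stopifnot(inherits(config, "run_config"))
  gm <- load_inputs(config)
  if (length(unique(gm$labels)) < 2L) {
    stop("build: need >= 2 breeds", call. = FALSE)
  }
  qc <- attr(gm, "qc")
  message(sprintf("QC: kept %d of %d SNPs (%d dropped for missingness, %d monomorphic)",
                  qc$n_kept, qc$n_input, qc$n_dropped_missing,
                  qc$n_dropped_monomorphic))
  tree <- build_tree(
    gm, topology = config$topology, k = config$k,
    n_clusters = config$n_clusters, n_top = config$n_top,
    p1_size = config$p1_size, tier_sizes = config$tier_sizes,
    gap_ratio = config$gap_ratio, seed = config$seed,
    root_name = config$root_name
  )
  dir.create(file.path(config$out_dir, "panels"),
             showWarnings = FALSE, recursive = TRUE)
  paths <- c(tree = file.path(config$out_dir, "tree.yaml"),
             qc = file.path(config$out_dir, "qc_summary.tsv"))
  write_tree_config(tree, paths[["tree"]])
  write.table(
    data.frame(rule = c("input", "dropped_missing", "dropped_monomorphic", "kept"),
               n_snps = c(qc$n_input, qc$n_dropped_missing,
                          qc$n_dropped_monomorphic, qc$n_kept)),
    paths[["qc"]], sep = "\t", quote = FALSE, row.names = FALSE
  )
  for (node in internal_nodes(tree)) {
    if (is.null(node$panels)) next
    p <- file.path(config$out_dir, "panels",
                   sprintf("panel_%s.tsv", safe_name(node$name)))
    write_panel(node$panels, p)
    paths[[paste0("panel_", node$name)]] <- p
    message(sprintf("node '%s': k = %d, panel tiers %s", node$name, node$k,
                    paste(node$tier_sizes, collapse = "/")))
  }
  invisible(list(tree = tree, gm = gm, paths = paths))
}

#' Run the leave-one-out cross-validation experiment
#'
#' Builds the tree (via [run_build()]) and evaluates it with [loocv()],
#' writing the per-node and per-breed report tables (TSV + JSON) into the
#' config's output directory.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `report` (the `eval_report`), `tree`,
#'   `gm` and `paths`.
#' @export
run_evaluate <- function(config) {
  built <- run_build(config)
  report <- loocv(built$gm, built$tree, modes = config$modes,
                  k_nn = config$k_nn)
  paths <- report_tables(report, config$out_dir)
  message(sprintf("loocv: %d samples, %d unassigned decisions",
                  length(unique(report$records$sample)),
                  sum(report$records$unassigned)))
  invisible(list(report = report, tree = built$tree, gm = built$gm,
                 paths = c(built$paths, paths)))
}

#' Classify unknown samples with a fitted tree
#'
#' Builds (or reuses) the reference tree, encodes the unknown samples
#' against the reference minor alleles, and classifies each by descending
#' the tree in the requested mode. A sample lacking a SNP required at any
#' node raises an error listing the missing SNP ids.
#'
#' @param config A [run_config()] describing the reference data.
#' @param unknown_ped,unknown_map PED/MAP paths of the unknown samples.
#' @param mode Classification mode (default the smallest deployable panel
#'   among the configured modes, falling back to `"full"`).
#' @param built Optional result of a previous [run_build()] call to reuse.
#' @return Invisibly, a data frame (also written to `assignments.tsv`) with
#'   `sample_id`, `predicted_breed` (or `"unassigned"`) and the decision
#'   `path`.
#' @export
run_classify <- function(config, unknown_ped, unknown_map, mode = NULL,
                         built = NULL) {
  built <- built %||% run_build(config)
  mode <- mode %||% {
    tiers <- intersect(c("P3", "P2", "P1"), config$modes)
    if (length(tiers)) tiers[1] else "full"
  }
  raw_u <- read_genotypes(unknown_ped, unknown_map)
  vals <- encode_with_reference(raw_u, built$gm)
  rows <- lapply(raw_u$sample_ids, function(sid) {
    res <- classify_sample(built$tree, vals[sid, ], mode = mode,
                           k_nn = config$k_nn, sample_id = sid)
    data.frame(
      sample_id = sid,
      predicted_breed = res$final,
      path = paste(
        vapply(res$path, function(d) sprintf("%s->%s", d$node, d$predicted), ""),
        collapse = ";"
      )
    )
  })
  out <- do.call(rbind, rows)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  write.table(out, file.path(config$out_dir, "assignments.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}

#' Encode unknown samples against a reference encoding
#'
#' Maps raw allele calls onto the reference's per-SNP minor-allele counts so
#' that unknown samples live in the same numeric space as the training data.
#' Every reference SNP must be present; an allele never seen at that SNP in
#' the reference is an error.
#'
#' @param raw A [raw_genotype_table()] of the unknown samples.
#' @param gm The reference `genotype_matrix`.
#' @return Numeric samples x SNPs matrix (`NA` = missing) over the
#'   reference SNP set.
#' @export
encode_with_reference <- function(raw, gm) {
  stopifnot(inherits(raw, "raw_genotype_table"), inherits(gm, "genotype_matrix"))
  ref_ids <- colnames(gm$values)
  absent <- setdiff(ref_ids, raw$snp_ids)
  if (length(absent)) {
    stop("unknown samples are missing reference SNPs: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  n <- length(raw$sample_ids)
  out <- matrix(NA_real_, n, length(ref_ids),
                dimnames = list(raw$sample_ids, ref_ids))
  for (s in ref_ids) {
    x1 <- raw$a1[, s]
    x2 <- raw$a2[, s]
    miss <- x1 == "0"
    seen <- unique(c(x1[!miss], x2[!miss]))
    legal <- c(gm$minor_allele[[s]], gm$major_allele[[s]])
    bad <- setdiff(seen, legal)
    if (length(bad)) {
      stop(sprintf("SNP %s: allele(s) %s not present in the reference",
                   s, paste(bad, collapse = ", ")), call. = FALSE)
    }
    v <- (x1 == gm$minor_allele[[s]]) + (x2 == gm$minor_allele[[s]])
    v[miss] <- NA_real_
    out[, s] <- v
  }
  out
}

# ---- tree config serialisation ----------------------------------------

topology_of_node <- function(node) {
  if (node$is_leaf) return(node$name)
  setNames(lapply(node$children, topology_of_node), names(node$children))
}

#' Write a tree's topology and per-node settings as YAML
#' @param tree A `breed_tree`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_tree_config <- function(tree, path) {
  nodes <- internal_nodes(tree)
  node_cfg <- setNames(lapply(nodes, function(nd) {
    list(k = nd$k,
         n_children = length(nd$children),
         tiers = as.list(nd$tier_sizes),
         breeds = nd$breeds)
  }), vapply(nodes, `[[`, "", "name"))
  yaml::write_yaml(
    list(root_name = tree$root$name,
         seed = tree$config$seed,
         topology = topology_of_node(tree$root),
         nodes = node_cfg),
    path
  )
  invisible(path)
}

#' Read a tree configuration written by [write_tree_config()]
#' @param path YAML path.
#' @return List with `topology`, `root_name`, `seed`, `k` (named integer
#'   vector) and `tier_sizes` (named list), directly usable as
#'   [build_tree()] arguments.
#' @export
read_tree_config <- function(path) {
  x <- yaml::read_yaml(path)
  k <- vapply(x$nodes, function(nd) as.integer(nd$k), integer(1))
  tiers <- lapply(x$nodes, function(nd) unlist(nd$tiers))
  list(topology = x$topology, root_name = x$root_name, seed = x$seed,
       k = k, tier_sizes = tiers)
}
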