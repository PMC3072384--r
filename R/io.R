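#' Raw diploid genotype table
#'
#' In-memory carrier for allele-character calls as read from PED/MAP files:
#' one pair of allele characters per sample per SNP, with `"0"` as the
#' missing-allele code (a call is missing if either allele is `"0"`; both are
#' then stored as `"0"`).
#'
#' @param sample_ids,family_ids Character vectors, one entry per sample;
#'   sample ids must be unique.
#' @param snp_ids Unique SNP ids in file (MAP) order.
#' @param a1,a2 Character matrices (samples x SNPs) of first/second alleles.
#' @param chrom,pos Optional per-SNP chromosome codes and base-pair positions.
#' @return An object of class `raw_genotype_table`.
#' @export
raw_genotype_table <- function(sample_ids, family_ids, snp_ids, a1, a2,
                               chrom = NULL, pos = NULL) {
  n <- length(sample_ids)
  m <- length(snp_ids)
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(snp_ids)) {
    stop("duplicate SNP ids: ",
         paste(unique(snp_ids[duplicated(snp_ids)]), collapse = ", "),
         call. = FALSE)
  }
  stopifnot(is.matrix(a1), is.matrix(a2),
            all(dim(a1) == c(n, m)), all(dim(a2) == c(n, m)),
            length(family_ids) == n)
  # normalise half-missing calls to fully missing
  miss <- a1 == "0" | a2 == "0"
  a1[miss] <- "0"
  a2[miss] <- "0"
  dimnames(a1) <- dimnames(a2) <- list(sample_ids, snp_ids)
  structure(
    list(sample_ids = sample_ids, family_ids = family_ids, snp_ids = snp_ids,
         a1 = a1, a2 = a2,
         chrom = chrom %||% rep("1", m),
         pos = pos %||% seq_len(m)),
    class = "raw_genotype_table"
  )
}

#' @export
print.raw_genotype_table <- function(x, ...) {
  cat(sprintf("raw_genotype_table: %d samples x %d SNPs\n",
              length(x$sample_ids), length(x$snp_ids)))
  invisible(x)
}

#' Read genotypes from PLINK-style PED/MAP text files
#'
#' The PED dialect expected is one sample per row: family id, sample id, four
#' placeholder columns, then two allele characters per SNP (`0 0` = missing).
#' The MAP file has one row per SNP: chromosome, SNP id, genetic distance,
#' position. SNP order is MAP-file order; malformed input is rejected, never
#' repaired.
#'
#' @param ped_path,map_path Paths to the PED and MAP files.
#' @return A [raw_genotype_table()].
#' @export
read_genotypes <- function(ped_path, map_path) {
  if (!file.exists(ped_path)) stop("PED file not found: ", ped_path, call. = FALSE)
  if (!file.exists(map_path)) stop("MAP file not found: ", map_path, call. = FALSE)

  map_lines <- readLines(map_path)
  map_lines <- map_lines[nzchar(trimws(map_lines))]
  map_fields <- strsplit(trimws(map_lines), "[ \t]+")
  bad <- which(lengths(map_fields) != 4L)
  if (length(bad)) {
    stop(sprintf("MAP parse error at line %d: expected 4 fields, got %d",
                 bad[1], lengths(map_fields)[bad[1]]), call. = FALSE)
  }
  chrom <- vapply(map_fields, `[[`, "", 1L)
  snp_ids <- vapply(map_fields, `[[`, "", 2L)
  pos <- as.integer(vapply(map_fields, `[[`, "", 4L))
  m <- length(snp_ids)

  ped_lines <- readLines(ped_path)
  ped_lines <- ped_lines[nzchar(trimws(ped_lines))]
  fields <- strsplit(trimws(ped_lines), "[ \t]+")
  want <- 6L + 2L * m
  bad <- which(lengths(fields) != want)
  if (length(bad)) {
    stop(sprintf("PED parse error at line %d: expected %d fields, got %d",
                 bad[1], want, lengths(fields)[bad[1]]), call. = FALSE)
  }
  n <- length(fields)
  family_ids <- vapply(fields, `[[`, "", 1L)
  sample_ids <- vapply(fields, `[[`, "", 2L)

  a1 <- matrix("0", n, m)
  a2 <- matrix("0", n, m)
  if (m > 0L) {
    idx1 <- 6L + 2L * seq_len(m) - 1L
    idx2 <- idx1 + 1L
    for (i in seq_len(n)) {
      a1[i, ] <- fields[[i]][idx1]
      a2[i, ] <- fields[[i]][idx2]
    }
  }
  raw_genotype_table(sample_ids, family_ids, snp_ids, a1, a2, chrom, pos)
}

#' Write a raw genotype table as PED/MAP files
#'
#' @param raw A [raw_genotype_table()].
#' @param ped_path,map_path Output paths.
#' @return Invisibly, `c(ped_path, map_path)`.
#' @export
write_ped <- function(raw, ped_path, map_path) {
  stopifnot(inherits(raw, "raw_genotype_table"))
  n <- length(raw$sample_ids)
  m <- length(raw$snp_ids)
  map_df <- data.frame(raw$chrom, raw$snp_ids, rep(0L, m), raw$pos)
  write.table(map_df, map_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  geno <- matrix("", n, 2L * m)
  if (m > 0L) {
    geno[, 2L * seq_len(m) - 1L] <- raw$a1
    geno[, 2L * seq_len(m)] <- raw$a2
  }
  lead <- cbind(raw$family_ids, raw$sample_ids, "0", "0", "0", "-9")
  lines <- do.call(paste, c(split(cbind(lead, geno),
                                  col(cbind(lead, geno))), sep = " "))
  writeLines(lines, ped_path)
  invisible(c(ped_path, map_path))
}

#' Read a sample-to-breed label table
#'
#' @param path Tab-separated file with header columns `sample_id` and
#'   `breed`.
#' @param samples Character vector of sample ids that must all be covered.
#' @return Named character vector mapping each of `samples` to its breed, in
#'   the order of `samples`.
#' @export
read_labels <- function(path, samples) {
  if (!file.exists(path)) stop("label file not found: ", path, call. = FALSE)
  df <- read.table(path, header = TRUE, sep = "\t", colClasses = "character")
  if (!all(c("sample_id", "breed") %in% names(df))) {
    stop("label file must have columns `sample_id` and `breed`", call. = FALSE)
  }
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample in label file: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "),
         call. = FALSE)
  }
  missing <- setdiff(samples, df$sample_id)
  if (length(missing)) {
    stop("label file is missing samples: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  setNames(df$breed[match(samples, df$sample_id)], samples)
}

#' Write a sample-to-breed label table
#' @param labels Named character vector (names = sample ids).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_labels <- function(labels, path) {
  write.table(
    data.frame(sample_id = names(labels), breed = unname(labels)),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Write a SNP panel as a tab-separated file
#'
#' Columns are `rank`, `snp_id`, `pcaim_score`, `node_name`, `tier`; the tier
#' token is the smallest panel tier (`P1`, `P2`, `P3`) containing the rank.
#' Scores are written with 17 significant digits so that
#' `read_panel(write_panel(p))` reproduces them exactly.
#'
#' @param panel An [snp_panel()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "snp_panel"))
  n <- length(panel$snp_ids)
  if (n == 0L) stop("panel is empty", call. = FALSE)
  tier <- tier_of_rank(seq_len(n), panel$tiers)
  df <- data.frame(
    rank = seq_len(n),
    snp_id = panel$snp_ids,
    pcaim_score = sprintf("%.17g", unname(panel$scores[panel$snp_ids])),
    node_name = panel$node,
    tier = tier
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

tier_of_rank <- function(rank, tiers) {
  out <- rep(names(tiers)[length(tiers)], length(rank))
  for (t in rev(seq_along(tiers))) out[rank <= tiers[t]] <- names(tiers)[t]
  out[rank > tiers[length(tiers)]] <- NA_character_
  out
}

#' Read a SNP panel written by [write_panel()]
#'
#' @param path Panel TSV path.
#' @return An [snp_panel()].
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop("panel file not found: ", path, call. = FALSE)
  df <- read.table(path, header = TRUE, sep = "\t",
                   colClasses = c("integer", "character", "character",
                                  "character", "character"))
  known <- c("P1", "P2", "P3")
  bad <- setdiff(unique(df$tier), known)
  if (length(bad)) {
    stop("unknown tier token in panel file: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!identical(df$rank, seq_len(nrow(df)))) {
    stop("panel ranks must be consecutive 1..n", call. = FALSE)
  }
  tiers <- vapply(known, function(t) {
    r <- df$rank[df$tier == t]
    if (length(r)) max(r) else NA_integer_
  }, integer(1))
  tiers <- tiers[!is.na(tiers)]
  snp_panel(
    node = df$node_name[1],
    snp_ids = df$snp_id,
    tiers = tiers,
    scores = setNames(as.numeric(df$pcaim_score), df$snp_id)
  )
}
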