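# TSV tables with '#'-prefixed metadata lines, aligned FASTA, Newick trees.

#' Write a TSV table with metadata header lines
#'
#' @param df data frame.
#' @param path output path.
#' @param meta character vector of metadata lines (written as `# <line>`).
#' @export
write_tsv <- function(df, path, meta = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(meta)) writeLines(paste0("# ", meta), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a TSV table, skipping '#' metadata lines
#'
#' @param path input path.
#' @return data frame.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read an internode count table and companions
#'
#' `counts_path`: columns `gene`, `i4`, `i5`, `i6`, `i8`.
#' `lib_sizes_path`: columns `internode`, `lib_size`.
#' `ambiguous_path` (optional): columns `gene_a`, `gene_b`, `internode`,
#' `count`.
#'
#' @param counts_path,lib_sizes_path,ambiguous_path file paths
#'   (`ambiguous_path` may be `NULL` or point to an empty table).
#' @return an [internode_counts] object.
#' @export
read_internode_counts <- function(counts_path, lib_sizes_path,
                                  ambiguous_path = NULL) {
  cts <- read_tsv(counts_path)
  libs <- read_tsv(lib_sizes_path)
  if (!all(c("internode", "lib_size") %in% names(libs)))
    stop(lib_sizes_path, ": needs columns internode, lib_size")
  ik <- as.character(libs$internode)
  ik[ik %in% c("4", "5", "6", "8")] <-
    paste0("i", ik[ik %in% c("4", "5", "6", "8")])
  lib <- setNames(libs$lib_size, ik)
  amb <- NULL
  if (!is.null(ambiguous_path) && file.exists(ambiguous_path)) {
    amb <- read_tsv(ambiguous_path)
    if (nrow(amb) == 0) amb <- NULL
  }
  internode_counts(cts, lib, amb)
}

#' Write an internode count object to TSV files
#'
#' @param x an [internode_counts] object.
#' @param dir output directory (created if needed).
#' @param meta metadata lines for all files.
#' @return named vector of the written paths.
#' @export
write_internode_counts <- function(x, dir, meta = character()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cts <- data.frame(gene = rownames(x$counts), x$counts,
                    row.names = NULL, check.names = FALSE)
  p1 <- file.path(dir, "counts.tsv")
  write_tsv(cts, p1, meta)
  p2 <- file.path(dir, "lib_sizes.tsv")
  write_tsv(data.frame(internode = names(x$lib_sizes),
                       lib_size = unname(x$lib_sizes)), p2, meta)
  p3 <- file.path(dir, "ambiguous.tsv")
  write_tsv(x$ambiguous, p3, meta)
  c(counts = p1, lib_sizes = p2, ambiguous = p3)
}

#' Read an aligned FASTA file
#'
#' @param path aligned FASTA (equal-length sequences; gaps as `-`).
#' @return named character vector of sequences.
#' @export
read_alignment <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  seqs <- as.character(x)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (length(unique(nchar(seqs))) > 1)
    stop(path, ": ragged alignment (unequal sequence lengths)")
  seqs
}

#' Write an aligned FASTA file
#'
#' @param seqs named character vector of equal-length sequences.
#' @param path output path.
#' @export
write_alignment <- function(seqs, path) {
  if (length(unique(nchar(seqs))) > 1)
    stop("refusing to write ragged alignment")
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path)
  invisible(path)
}

#' Write a tree with bootstrap node labels as Newick
#'
#' @param tree `phylo` object (node labels = supports, `NA` allowed).
#' @param path output path.
#' @export
write_tree <- function(tree, path) {
  if (!is.null(tree$node.label))
    tree$node.label <- ifelse(is.na(tree$node.label), "",
                              format(tree$node.label, trim = TRUE))
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read annotations table
#'
#' Columns: `gene`, `species`, `family`, optionally `subgroup` (anchor
#' label) and `wall_context` (`primary` / `secondary` for reference genes).
#'
#' @param path input path.
#' @return data frame with the optional columns filled with `NA` if absent.
#' @export
read_annotations <- function(path) {
  a <- read_tsv(path)
  need <- c("gene", "species", "family")
  if (!all(need %in% names(a)))
    stop(path, ": needs columns ", paste(need, collapse = ", "))
  for (col in c("subgroup", "wall_context"))
    if (!col %in% names(a)) a[[col]] <- NA_character_
  a$subgroup[a$subgroup %in% c("", "NA")] <- NA
  a$wall_context[a$wall_context %in% c("", "NA")] <- NA
  a
}
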