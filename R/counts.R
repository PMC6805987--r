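#' Internode count matrix
#'
#' Container for raw unique-read counts of genes across the four profiled
#' stem internodes (4, 5, 6 and 8; internode 7 is excluded by design and is
#' never accepted), together with per-internode library sizes and, optionally,
#' counts of reads that mapped ambiguously to exactly two duplicated loci.
#'
#' @param counts numeric matrix or data frame, genes x internodes. Columns
#'   must be exactly `i4`, `i5`, `i6`, `i8` (any order); row names (or a
#'   `gene` column) give unique gene ids. Counts must be non-negative.
#'   Fractional values are permitted so that ambiguous-read splitting can
#'   round-trip through the container.
#' @param lib_sizes named numeric vector of length 4 (names `i4`, `i5`, `i6`,
#'   `i8`): total mapped reads per internode library. All must be positive.
#' @param ambiguous data frame with columns `gene_a`, `gene_b`, `internode`,
#'   `count`, one row per duplicated pair per internode, or `NULL` for none.
#'   `internode` may be given as 4/5/6/8 or "i4".."i8".
#'
#' @return an object of class `internode_counts`: a list with elements
#'   `counts` (numeric matrix), `lib_sizes` (named numeric) and `ambiguous`
#'   (data frame, possibly empty).
#' @export
internode_counts <- function(counts, lib_sizes, ambiguous = NULL) {
  internodes <- c("i4", "i5", "i6", "i8")
  if (is.data.frame(counts)) {
    if ("gene" %in% names(counts)) {
      rn <- as.character(counts$gene)
      counts <- counts[, setdiff(names(counts), "gene"), drop = FALSE]
      counts <- as.matrix(counts)
      rownames(counts) <- rn
    } else {
      counts <- as.matrix(counts)
    }
  }
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("`counts` must be a numeric matrix or data frame")
  bad <- setdiff(colnames(counts), internodes)
  if (length(bad))
    stop("internode column(s) not allowed: ", paste(bad, collapse = ", "),
         " (internode set is exactly {i4, i5, i6, i8})")
  if (!setequal(colnames(counts), internodes))
    stop("`counts` must have columns i4, i5, i6, i8; missing: ",
         paste(setdiff(internodes, colnames(counts)), collapse = ", "))
  counts <- counts[, internodes, drop = FALSE]
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts)))
    stop("`counts` needs unique gene ids as row names")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("`counts` must be finite and non-negative")

  lib_sizes <- unlist(lib_sizes)
  if (length(lib_sizes) != 4)
    stop("`lib_sizes` must have exactly 4 entries (one per internode)")
  if (is.null(names(lib_sizes)) || !setequal(names(lib_sizes), internodes))
    names(lib_sizes) <- internodes
  lib_sizes <- lib_sizes[internodes]
  if (any(!is.finite(lib_sizes)) || any(lib_sizes <= 0))
    stop("`lib_sizes` must be positive")

  ambiguous <- normalize_ambiguous(ambiguous, rownames(counts))

  structure(list(counts = counts, lib_sizes = lib_sizes,
                 ambiguous = ambiguous),
            class = "internode_counts")
}

# canonical empty/validated ambiguous-pair table
normalize_ambiguous <- function(ambiguous, genes) {
  empty <- data.frame(gene_a = character(), gene_b = character(),
                      internode = character(), count = numeric(),
                      stringsAsFactors = FALSE)
  if (is.null(ambiguous) || nrow(ambiguous) == 0) return(empty)
  need <- c("gene_a", "gene_b", "internode", "count")
  if (!all(need %in% names(ambiguous)))
    stop("`ambiguous` needs columns gene_a, gene_b, internode, count")
  amb <- ambiguous[, need]
  amb$gene_a <- as.character(amb$gene_a)
  amb$gene_b <- as.character(amb$gene_b)
  ik <- as.character(amb$internode)
  ik[ik %in% c("4", "5", "6", "8")] <- paste0("i", ik[ik %in% c("4", "5", "6", "8")])
  amb$internode <- ik
  if (!all(amb$internode %in% c("i4", "i5", "i6", "i8")))
    stop("`ambiguous$internode` outside the {4,5,6,8} internode set")
  unknown <- setdiff(unique(c(amb$gene_a, amb$gene_b)), genes)
  if (length(unknown))
    stop("ambiguous pair references unknown gene(s): ",
         paste(unknown, collapse = ", "))
  if (any(amb$gene_a == amb$gene_b))
    stop("ambiguous pair with gene_a == gene_b")
  if (any(!is.finite(amb$count)) || any(amb$count < 0))
    stop("`ambiguous$count` must be finite and non-negative")
  rownames(amb) <- NULL
  amb
}

#' @export
print.internode_counts <- function(x, ...) {
  cat(sprintf("internode_counts: %d genes x 4 internodes (i4, i5, i6, i8)\n",
              nrow(x$counts)))
  cat(sprintf("  library sizes: %s\n",
              paste(sprintf("%s=%.4g", names(x$lib_sizes), x$lib_sizes),
                    collapse = " ")))
  cat(sprintf("  ambiguous pair entries: %d\n", nrow(x$ambiguous)))
  invisible(x)
}
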