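# Alignment handling ---------------------------------------------------------

# Coerce an alignment (named character vector, AAStringSet, or character
# matrix) to a residue matrix: one row per sequence, one column per site.
as_aln_matrix <- function(aln) {
  if (inherits(aln, "XStringSet")) aln <- as.character(aln)
  if (is.matrix(aln) && is.character(aln)) {
    m <- aln
  } else if (is.character(aln)) {
    if (is.null(names(aln)) || anyDuplicated(names(aln)))
      stop("alignment sequences need unique names")
    if (length(unique(nchar(aln))) > 1)
      stop("ragged alignment: sequences differ in length")
    m <- do.call(rbind, strsplit(aln, "", fixed = TRUE))
    rownames(m) <- names(aln)
  } else stop("unsupported alignment representation")
  if (nrow(m) < 1 || ncol(m) < 1) stop("empty alignment")
  if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
    stop("alignment sequences need unique names")
  toupper(m)
}

#' Pairwise p-distances with pairwise gap deletion
#'
#' Entry (i, j) is the proportion of differing residues over sites where
#' neither sequence has a gap (`-`). If a pair shares no comparable site the
#' distance is set to 1 and a warning is raised.
#'
#' @param aln alignment: a named character vector of equal-length strings, a
#'   `Biostrings::AAStringSet`, or a residue matrix.
#' @return symmetric numeric matrix with zero diagonal, entries in `[0, 1]`,
#'   dimnames = sequence ids.
#' @export
p_distance <- function(aln) {
  m <- as_aln_matrix(aln)
  if (nrow(m) < 2) stop("p_distance needs at least 2 sequences")
  p_distance_core(m)
}

p_distance_core <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  gap <- m == "-"
  none_comparable <- FALSE
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !gap[i, ] & !gap[j, ]
      nc <- sum(ok)
      if (nc == 0) {
        d[i, j] <- d[j, i] <- 1
        none_comparable <- TRUE
      } else {
        pd <- sum(m[i, ok] != m[j, ok]) / nc
        d[i, j] <- d[j, i] <- pd
      }
    }
  }
  if (none_comparable)
    warning("sequence pair(s) with no comparable (gap-free) sites: ",
            "distance set to 1")
  d
}

# Neighbor joining ------------------------------------------------------------

#' Neighbor-joining tree
#'
#' Standard Saitou-Nei agglomeration: at each step the pair minimizing the
#' Q-criterion is joined, with branch lengths from the usual rate estimates.
#' Determinism under ties: the pair with the lowest (row, column) index in
#' the current working matrix is taken. Negative branch-length estimates are
#' clamped to zero with the deficit transferred to the sister branch. The
#' result is the unrooted tree, returned as an [ape::phylo] object rooted at
#' the final (trifurcating) join.
#'
#' @param d symmetric distance matrix with dimnames, or a `dist` object.
#' @return an `ape` `phylo` object with branch lengths (non-negative).
#' @export
nj_tree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || !is.numeric(d)) stop("`d` must be a numeric matrix")
  ids <- rownames(d)
  if (is.null(ids)) stop("`d` needs gene ids as dimnames")
  n <- nrow(d)
  if (n < 3) stop("neighbor joining needs at least 3 taxa")
  if (max(abs(d - t(d))) > 1e-9) stop("`d` must be symmetric")

  fmt <- function(x) sprintf("%.15g", max(x, 0))
  # working state: subtree newick strings, one per active node
  nwk <- ids
  D <- d
  while (length(nwk) > 3) {
    r <- nrow(D)
    rs <- rowSums(D)
    Q <- (r - 2) * D - outer(rs, rs, `+`)
    Q[lower.tri(Q, diag = TRUE)] <- Inf
    hit <- which(Q == min(Q), arr.ind = TRUE)
    hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
    i <- hit[1, 1]; j <- hit[1, 2]
    vi <- D[i, j] / 2 + (rs[i] - rs[j]) / (2 * (r - 2))
    vj <- D[i, j] - vi
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- max(vi + vj, 0); vj <- 0 }
    merged <- paste0("(", nwk[i], ":", fmt(vi), ",", nwk[j], ":", fmt(vj), ")")
    dn <- (D[i, ] + D[j, ] - D[i, j]) / 2
    dn <- pmax(dn[-c(i, j)], 0)
    D <- D[-c(i, j), -c(i, j), drop = FALSE]
    D <- rbind(cbind(D, dn), c(dn, 0))
    nwk <- c(nwk[-c(i, j)], merged)
  }
  x1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  x2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  x3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  txt <- paste0("(", nwk[1], ":", fmt(x1), ",", nwk[2], ":", fmt(x2), ",",
                nwk[3], ":", fmt(x3), ");")
  ape::read.tree(text = txt)
}

# Bootstrap -------------------------------------------------------------------

#' Bootstrap supports for a neighbor-joining family tree
#'
#' Alignment columns are resampled with replacement; each replicate runs
#' [p_distance()] and [nj_tree()]. The support of each internal edge of the
#' tree built from the full alignment is the percentage of replicates whose
#' tree contains the same leaf bipartition. Supports are attached as node
#' labels of the returned tree (the basal trifurcation, which carries no
#' bipartition of its own, gets `NA`). The conventional number of replicates
#' is 1000; tests typically use 100.
#'
#' @param aln alignment as in [p_distance()], with at least 4 sequences
#'   (3-taxon trees have no internal edge).
#' @param n_reps number of bootstrap replicates (default 1000).
#' @param seed optional integer seed for reproducible resampling.
#' @return `phylo` object with numeric `node.label` supports in `[0, 100]`.
#' @export
bootstrap_support <- function(aln, n_reps = 1000, seed = NULL) {
  m <- as_aln_matrix(aln)
  if (nrow(m) < 3) stop("bootstrap_support needs at least 3 sequences")
  if (n_reps < 1) stop("n_reps must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  ref <- nj_tree(p_distance_core(m))
  L <- ncol(m)
  reps <- vector("list", n_reps)
  for (b in seq_len(n_reps)) {
    cols <- sample.int(L, L, replace = TRUE)
    reps[[b]] <- nj_tree(p_distance_core(m[, cols, drop = FALSE]))
  }
  counts <- ape::prop.clades(ref, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0
  supp <- 100 * counts / n_reps
  supp[1] <- NA  # basal node: the trivial all-taxa "bipartition"
  ref$node.label <- supp
  ref
}
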