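# Shared fixtures built in code.

# tiny count object: two genes, optional ambiguous pairs
make_counts <- function(g = c("gA", "gB"),
                        m = rbind(c(10, 10, 10, 10), c(30, 30, 30, 30)),
                        lib = c(i4 = 2e7, i5 = 2e7, i6 = 2e7, i8 = 2e7),
                        amb = NULL) {
  rownames(m) <- g
  colnames(m) <- c("i4", "i5", "i6", "i8")
  internode_counts(m, lib, amb)
}

# random count fixture with duplicated pairs, for conservation properties
random_counts <- function(n_genes = 6, n_pairs = 2) {
  g <- sprintf("g%02d", seq_len(n_genes))
  m <- matrix(rpois(n_genes * 4, 50), n_genes, 4,
              dimnames = list(g, c("i4", "i5", "i6", "i8")))
  amb <- NULL
  n_pairs <- min(n_pairs, floor(n_genes / 2))
  if (n_pairs > 0) {
    pick <- matrix(sample(g, 2 * n_pairs), ncol = 2)
    amb <- do.call(rbind, lapply(seq_len(n_pairs), function(k)
      data.frame(gene_a = pick[k, 1], gene_b = pick[k, 2],
                 internode = sample(c("i4", "i5", "i6", "i8"), 1),
                 count = sample(0:20, 1), stringsAsFactors = FALSE)))
  }
  internode_counts(m, c(i4 = 2e7, i5 = 2e7, i6 = 2e7, i8 = 2e7), amb)
}

# alignment in which every internal edge of a known tree is marked by a
# block of `cols_per_edge` congruent columns (plus tip-private blocks),
# so bootstrap supports are expected at 100 throughout
congruent_alignment <- function(cols_per_edge = 30) {
  taxa <- c("t1", "t2", "t3", "t4", "t5", "t6")
  # clades: {t1,t2}, {t3,t4}, {t5,t6} around a central node
  groups <- list(c("t1", "t2"), c("t3", "t4"), c("t5", "t6"))
  blocks <- list()
  for (grp in groups) {
    col <- ifelse(taxa %in% grp, "W", "A")
    blocks[[length(blocks) + 1]] <-
      matrix(col, length(taxa), cols_per_edge)
  }
  for (k in seq_along(taxa)) {  # tip-private signal
    col <- ifelse(taxa == taxa[k], "Y", "G")
    blocks[[length(blocks) + 1]] <- matrix(col, length(taxa), 5)
  }
  m <- do.call(cbind, blocks)
  setNames(apply(m, 1, paste, collapse = ""), taxa)
}

# additive distance matrix from a random tree; returns both
random_additive <- function(n = 8) {
  tr <- ape::rtree(n, br = function(k) runif(k, 0.1, 1))
  list(tree = tr, d = ape::cophenetic.phylo(tr))
}
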