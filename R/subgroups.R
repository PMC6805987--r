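# Bipartition bookkeeping ----------------------------------------------------

# All bipartition sides of an unrooted tree stored as a rooted phylo:
# for every edge, the set of tips on the child side, with the bootstrap
# support of that edge (100 for the trivial tip-edge bipartitions; internal
# edges take the child's node label, or 100 when the tree is unlabelled).
# Internal edges of (numerically) zero length carry no resolution and are
# treated as unsupported (support 0), which collapses them to polytomies
# for assignment purposes.
tree_bipartitions <- function(tree) {
  n <- length(tree$tip.label)
  pp <- ape::prop.part(tree)
  labs <- tree$node.label
  sides <- list(); supp <- numeric(0); kind <- character(0)
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2]
    if (child <= n) {
      sides[[length(sides) + 1]] <- tree$tip.label[child]
      supp <- c(supp, 100)
      kind <- c(kind, "tip")
    } else {
      tips <- tree$tip.label[pp[[child - n]]]
      s <- if (is.null(labs)) 100 else suppressWarnings(as.numeric(labs[child - n]))
      if (is.na(s)) s <- 0
      if (!is.null(tree$edge.length) && tree$edge.length[e] <= 1e-12) s <- 0
      sides[[length(sides) + 1]] <- tips
      supp <- c(supp, s)
      kind <- c(kind, "internal")
    }
  }
  list(sides = sides, support = supp, kind = kind, tips = tree$tip.label)
}

#' Assign genes to family subgroups using labeled anchors
#'
#' Each non-anchor gene is assigned the subgroup label `L` when the smallest
#' bipartition side of the tree that contains the gene and at least one
#' anchor contains anchors of only the label `L` and that bipartition has
#' bootstrap support of at least `min_support`; otherwise the gene is
#' `"unassigned"`. Anchors always keep their own label. Internal edges with
#' zero branch length are treated as unresolved (support 0), so a star-like
#' tree (e.g. from identical sequences) yields no supported assignments.
#'
#' @param tree a `phylo` object, typically from [bootstrap_support()]
#'   (node labels = supports). An unlabelled tree is accepted and its
#'   resolved internal edges are treated as fully supported.
#' @param anchors data frame with columns `gene` and `subgroup` (extra
#'   columns such as `species` are kept and used by
#'   [flag_species_absent()]).
#' @param min_support minimal bootstrap support (percentage) for the clade
#'   backing an assignment; default 50.
#' @return data frame with columns `gene`, `subgroup`, `support`,
#'   `is_anchor`, one row per tree tip.
#' @export
assign_subgroups <- function(tree, anchors, min_support = 50) {
  stopifnot(inherits(tree, "phylo"))
  if (!all(c("gene", "subgroup") %in% names(anchors)))
    stop("`anchors` needs columns gene and subgroup")
  anchors <- anchors[!is.na(anchors$subgroup), , drop = FALSE]
  if (nrow(anchors) == 0) stop("no anchors supplied")
  missing <- setdiff(anchors$gene, tree$tip.label)
  if (length(missing))
    stop("anchor(s) absent from tree: ", paste(missing, collapse = ", "))
  alab <- setNames(as.character(anchors$subgroup), anchors$gene)

  bp <- tree_bipartitions(tree)
  tips <- bp$tips
  out <- data.frame(gene = tips,
                    subgroup = NA_character_,
                    support = NA_real_,
                    is_anchor = tips %in% names(alab),
                    stringsAsFactors = FALSE)
  # candidate sides per edge: child side and its complement
  cand_sides <- c(bp$sides, lapply(bp$sides, function(s) setdiff(tips, s)))
  cand_supp <- c(bp$support, bp$support)

  for (g in tips) {
    if (g %in% names(alab)) {
      out$subgroup[out$gene == g] <- alab[[g]]
      out$support[out$gene == g] <- 100
      next
    }
    keep <- vapply(cand_sides,
                   function(s) g %in% s && any(s %in% names(alab)),
                   logical(1))
    if (!any(keep)) { out$subgroup[out$gene == g] <- "unassigned"; next }
    sz <- vapply(cand_sides[keep], length, integer(1))
    sp <- cand_supp[keep]
    key <- vapply(cand_sides[keep],
                  function(s) paste(sort(s), collapse = "|"), character(1))
    ord <- order(sz, -sp, key)
    side <- cand_sides[keep][[ord[1]]]
    supp <- sp[ord[1]]
    labs_in <- unique(alab[intersect(side, names(alab))])
    if (length(labs_in) == 1 && supp >= min_support) {
      out$subgroup[out$gene == g] <- labs_in
      out$support[out$gene == g] <- supp
    } else {
      out$subgroup[out$gene == g] <- "unassigned"
    }
  }
  out
}

#' Flag subgroups missing a species
#'
#' Given subgroup assignments and a gene -> species annotation, reports for
#' every subgroup the species of the configured set with no member in that
#' subgroup (anchors plus assigned genes). This captures lineage-specific
#' subgroups such as the grass-only or eudicot-only clades of the
#' cellulose-synthase-like family.
#'
#' @param assignments output of [assign_subgroups()].
#' @param annotations data frame with columns `gene` and `species`.
#' @param species_set character vector of species to check; defaults to all
#'   species present in `annotations`.
#' @return data frame with columns `subgroup`, `species_absent`
#'   (comma-separated, `""` when none).
#' @export
flag_species_absent <- function(assignments, annotations, species_set = NULL) {
  sp <- setNames(as.character(annotations$species), annotations$gene)
  if (is.null(species_set)) species_set <- sort(unique(sp))
  subs <- setdiff(unique(assignments$subgroup), c(NA, "unassigned"))
  res <- lapply(subs, function(s) {
    genes <- assignments$gene[assignments$subgroup == s]
    present <- unique(sp[genes[genes %in% names(sp)]])
    data.frame(subgroup = s,
               species_absent = paste(setdiff(species_set, present),
                                      collapse = ","),
               stringsAsFactors = FALSE)
  })
  if (length(res) == 0)
    return(data.frame(subgroup = character(), species_absent = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, c(res, list(make.row.names = FALSE)))
}

#' Closest reference-species homolog by alignment identity
#'
#' Returns the reference-species sequence with the highest pairwise identity
#' (1 - p-distance) to the query. Ties are broken by lexicographic gene id,
#' with a warning.
#'
#' @param query gene id present in the alignment.
#' @param aln alignment as in [p_distance()].
#' @param annotations data frame with columns `gene` and `species`.
#' @param reference_species species label of the reference set (default
#'   `"Ath"`).
#' @return one-row data frame: `gene` (query), `ref_gene`, `identity`.
#' @export
closest_homolog <- function(query, aln, annotations,
                            reference_species = "Ath") {
  m <- as_aln_matrix(aln)
  if (!query %in% rownames(m)) stop("query ", query, " not in alignment")
  refs <- annotations$gene[annotations$species == reference_species]
  refs <- setdiff(intersect(refs, rownames(m)), query)
  if (length(refs) == 0)
    stop("no ", reference_species, " reference sequences in alignment")
  d <- p_distance_core(m[c(query, refs), , drop = FALSE])
  ident <- 1 - d[query, refs]
  best <- max(ident)
  hits <- sort(names(ident)[ident == best])
  if (length(hits) > 1)
    warning("query ", query, " equidistant to ",
            paste(hits, collapse = ", "), "; taking ", hits[1])
  data.frame(gene = query, ref_gene = hits[1], identity = unname(best),
             stringsAsFactors = FALSE)
}

#' Closest homolog for every query-species gene in an alignment
#'
#' Vectorized convenience over [closest_homolog()] for the pipeline.
#'
#' @inheritParams closest_homolog
#' @param query_species species label of the query genes (default `"Zma"`).
#' @return data frame with columns `gene`, `ref_gene`, `identity`.
#' @export
closest_homologs <- function(aln, annotations, query_species = "Zma",
                             reference_species = "Ath") {
  m <- as_aln_matrix(aln)
  queries <- intersect(annotations$gene[annotations$species == query_species],
                       rownames(m))
  res <- lapply(queries, function(q)
    closest_homolog(q, m, annotations, reference_species))
  if (length(res) == 0)
    return(data.frame(gene = character(), ref_gene = character(),
                      identity = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, c(res, list(make.row.names = FALSE)))
}
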