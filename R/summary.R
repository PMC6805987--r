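#' Summarize one gene family
#'
#' The family-table row contract: total genes annotated to the family,
#' number expressed (summed normalized reads reaching the expression
#' threshold, i.e. tier `expressed` or `ratio_evaluable`), and counts of
#' elongation / transitional / secondary classes among ratio-evaluable
#' genes. Genes expressed but below the ratio threshold contribute to the
#' expressed count only, so the class counts may sum to less than the
#' expressed count.
#'
#' @param calls expression calls from [profile_expression()].
#' @param annotations data frame with columns `gene` and `family` (only
#'   query-species genes should carry counts; annotation rows without calls
#'   count toward `n_total` only). If `family` is a factor, its levels
#'   define the family universe, so a level without genes is a valid,
#'   empty family.
#' @param family family label to summarize.
#' @return one-row data frame: `family`, `n_total`, `n_expressed`,
#'   `n_elongation`, `n_transitional`, `n_secondary`.
#' @export
summarize_family <- function(calls, annotations, family) {
  known <- if (is.factor(annotations$family)) levels(annotations$family)
           else unique(annotations$family)
  if (!family %in% known)
    stop("unknown family: ", family)
  genes <- annotations$gene[annotations$family == family]
  cc <- calls[calls$gene %in% genes, , drop = FALSE]
  ev <- cc[cc$tier == "ratio_evaluable", , drop = FALSE]
  data.frame(family = family,
             n_total = length(genes),
             n_expressed = sum(cc$tier %in% c("expressed", "ratio_evaluable")),
             n_elongation = sum(ev$class == "elongation"),
             n_transitional = sum(ev$class == "transitional"),
             n_secondary = sum(ev$class == "secondary"),
             stringsAsFactors = FALSE)
}

#' Summarize all families
#'
#' One row per family in annotation order of first appearance. Genes with
#' calls but no annotation are gathered into an `"unannotated"` overflow row
#' with a warning. Global totals (attribute `totals`) equal the column sums,
#' so the summary is additive over families plus overflow.
#'
#' @inheritParams summarize_family
#' @return data frame of family rows (plus overflow when needed), with a
#'   `totals` attribute (named numeric).
#' @export
summarize_all <- function(calls, annotations) {
  fams <- if (is.factor(annotations$family)) levels(annotations$family)
          else unique(annotations$family)
  rows <- lapply(fams, function(f) summarize_family(calls, annotations, f))
  orphan <- setdiff(calls$gene, annotations$gene)
  if (length(orphan)) {
    warning(length(orphan), " gene(s) with calls but no annotation; ",
            "reported in an 'unannotated' overflow row")
    cc <- calls[calls$gene %in% orphan, , drop = FALSE]
    ev <- cc[cc$tier == "ratio_evaluable", , drop = FALSE]
    rows[[length(rows) + 1]] <-
      data.frame(family = "unannotated",
                 n_total = length(orphan),
                 n_expressed = sum(cc$tier %in%
                                     c("expressed", "ratio_evaluable")),
                 n_elongation = sum(ev$class == "elongation"),
                 n_transitional = sum(ev$class == "transitional"),
                 n_secondary = sum(ev$class == "secondary"),
                 stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "totals") <- colSums(out[, -1])
  out
}

#' Expand a family summary into stub per-gene calls
#'
#' The inverse of [summarize_all()] up to gene identity: for each family
#' row, stub genes named `<family>_g<i>` are created with classes matching
#' the class counts, tier `expressed` for expressed-but-not-evaluable genes
#' and `below_detection` for the rest. Re-summarizing the expansion
#' reproduces the input rows exactly (round-trip idempotence), which is how
#' published family-level count tables are audited against the counting
#' logic without per-gene data.
#'
#' @param summary data frame with columns `family`, `n_total`,
#'   `n_expressed`, `n_elongation`, `n_transitional`, `n_secondary`.
#' @return list with `calls` (stub expression calls: `gene`, `tier`,
#'   `ratio`, `class`) and `annotations` (`gene`, `family`).
#' @export
expand_summary <- function(summary) {
  need <- c("family", "n_total", "n_expressed", "n_elongation",
            "n_transitional", "n_secondary")
  if (!all(need %in% names(summary)))
    stop("summary must have columns ", paste(need, collapse = ", "))
  bad <- with(summary,
              n_elongation + n_transitional + n_secondary > n_expressed |
                n_expressed > n_total)
  if (any(bad))
    stop("summary row(s) violate the count chain (classes <= expressed <= ",
         "total): ", paste(summary$family[bad], collapse = ", "))
  calls <- list(); ann <- list()
  # representative ratios per class, within the class intervals
  rat <- c(elongation = 0.5, transitional = 1.5, secondary = 4)
  for (k in seq_len(nrow(summary))) {
    s <- summary[k, ]
    cls <- c(rep("elongation", s$n_elongation),
             rep("transitional", s$n_transitional),
             rep("secondary", s$n_secondary))
    n_ev <- length(cls)
    tier <- c(rep("ratio_evaluable", n_ev),
              rep("expressed", s$n_expressed - n_ev),
              rep("below_detection", s$n_total - s$n_expressed))
    gene <- sprintf("%s_g%03d", gsub("[^A-Za-z0-9]+", "_", s$family),
                    seq_len(s$n_total))
    calls[[k]] <- data.frame(
      gene = gene, tier = tier,
      ratio = c(rat[cls], rep(NA_real_, s$n_total - n_ev)),
      class = c(cls, rep("unclassified", s$n_total - n_ev)),
      stringsAsFactors = FALSE)
    ann[[k]] <- data.frame(gene = gene, family = s$family,
                           stringsAsFactors = FALSE)
  }
  list(calls = do.call(rbind, c(calls, list(make.row.names = FALSE))),
       annotations = do.call(rbind, c(ann, list(make.row.names = FALSE))))
}

#' Ratio-ordered gene listing for a family
#'
#' Ratio-evaluable genes of a family ordered by decreasing
#' secondary/primary expression ratio (the ordering used for per-family
#' expression dot plots).
#'
#' @inheritParams summarize_family
#' @return data frame of the family's evaluable calls, ratio-descending.
#' @export
family_gene_listing <- function(calls, annotations, family) {
  genes <- annotations$gene[annotations$family == family]
  ev <- calls[calls$gene %in% genes & calls$tier == "ratio_evaluable", ,
              drop = FALSE]
  ev[order(-ev$ratio, ev$gene), , drop = FALSE]
}
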