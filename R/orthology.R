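#' Map an expression class to a wall context
#'
#' Elongation-class genes act in the primary-wall (elongating) context,
#' secondary-class genes in the secondary-wall context. Transitional genes
#' have no single context.
#'
#' @param class character vector of expression classes.
#' @return character vector over `{primary, secondary, NA}`.
#' @export
class_context <- function(class) {
  ifelse(class == "elongation", "primary",
         ifelse(class == "secondary", "secondary", NA_character_))
}

#' Call putative orthologs by shared developmental context
#'
#' A query gene and its closest reference-species homolog are called
#' putative orthologs when the gene's expression class and the reference
#' gene's annotated wall context agree (elongation with primary, secondary
#' with secondary). Opposite contexts give `context_mismatch`. Transitional
#' query genes, and reference genes with unknown context (warned), give
#' `indeterminate`: such pairs are homologous but the criterion cannot
#' polarize them.
#'
#' @param calls expression calls from [profile_expression()]; only
#'   ratio-evaluable genes are eligible (others are dropped).
#' @param homologs data frame from [closest_homologs()] (`gene`, `ref_gene`,
#'   `identity`).
#' @param annotations data frame with columns `gene` and `wall_context` for
#'   reference genes (`primary` / `secondary` / `unknown` or `NA`).
#' @return data frame: `gene`, `ref_gene`, `identity`, `class`,
#'   `ref_context`, `verdict`.
#' @export
call_orthologs <- function(calls, homologs, annotations) {
  ev <- calls[calls$tier == "ratio_evaluable", c("gene", "class")]
  x <- merge(ev, homologs, by = "gene")
  ctx <- setNames(as.character(annotations$wall_context), annotations$gene)
  x$ref_context <- unname(ctx[x$ref_gene])
  x$ref_context[is.na(x$ref_context)] <- "unknown"
  verdict <- character(nrow(x))
  unknown_refs <- 0L
  for (k in seq_len(nrow(x))) {
    if (x$ref_context[k] == "unknown") {
      verdict[k] <- "indeterminate"; unknown_refs <- unknown_refs + 1L
    } else if (x$class[k] == "transitional") {
      verdict[k] <- "indeterminate"
    } else if (identical(class_context(x$class[k]), x$ref_context[k])) {
      verdict[k] <- "putative_ortholog"
    } else {
      verdict[k] <- "context_mismatch"
    }
  }
  if (unknown_refs > 0)
    warning(unknown_refs, " reference gene(s) with unknown wall context: ",
            "verdict set to indeterminate")
  x$verdict <- verdict
  x[order(x$gene), c("gene", "ref_gene", "identity", "class",
                     "ref_context", "verdict")]
}

#' Fraction of putative orthologs
#'
#' Proportion of ortholog calls with verdict `putative_ortholog` within a
#' class-restricted set, reported with its numerator and denominator.
#' Because transitional genes receive `indeterminate` verdicts, the
#' denominator can be taken either over all calls in the restriction
#' (`include_indeterminate = TRUE`, default) or over determinate calls only.
#'
#' @param ortho ortholog calls from [call_orthologs()].
#' @param restrict_to_class optional class (`"secondary"`, `"elongation"`,
#'   `"transitional"`) to restrict to.
#' @param include_indeterminate keep indeterminate calls in the denominator?
#' @return list with `fraction`, `n_putative`, `n_total`.
#' @export
ortholog_fraction <- function(ortho, restrict_to_class = NULL,
                              include_indeterminate = TRUE) {
  x <- ortho
  if (!is.null(restrict_to_class))
    x <- x[x$class %in% restrict_to_class, , drop = FALSE]
  if (!include_indeterminate)
    x <- x[x$verdict != "indeterminate", , drop = FALSE]
  if (nrow(x) == 0) stop("empty restriction: no ortholog calls to summarize")
  n_put <- sum(x$verdict == "putative_ortholog")
  list(fraction = n_put / nrow(x), n_putative = n_put, n_total = nrow(x))
}
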