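#' Expression thresholds
#'
#' The detection / expression / ratio-evaluation criteria applied to
#' normalized internode counts, all on the reads-per-20-million scale.
#' Defaults are the criteria used for maize stem rind internodes: one read
#' per million (20 per 20 M) for detection of a transcript in an internode,
#' a summed 95 reads per 20 M over the four internodes as the minimal
#' criterion of expression, a summed 500 reads per 20 M to qualify for an
#' expression ratio, and ratio cut points at 1 and 2 separating elongation
#' (primary-wall), transitional, and secondary-wall classes.
#'
#' @param detect_per_million per-internode detection threshold in reads per
#'   million (default 1, i.e. 20 per 20 M).
#' @param expressed_min summed reads per 20 M over the four internodes at or
#'   above which a gene is called expressed (default 95; inclusive).
#' @param ratio_min summed reads per 20 M at or above which a gene qualifies
#'   for ratio evaluation (default 500; inclusive).
#' @param secondary_min_ratio ratio at or above which a gene is classed
#'   secondary (default 2; inclusive).
#' @param primary_max_ratio ratio below which a gene is classed elongation
#'   (default 1; exclusive, so ratio 1 is transitional).
#' @param normalization_base library size the normalized scale refers to
#'   (default 2e7 reads).
#' @return a list of class `wall_thresholds`.
#' @export
thresholds <- function(detect_per_million = 1,
                       expressed_min = 95,
                       ratio_min = 500,
                       secondary_min_ratio = 2,
                       primary_max_ratio = 1,
                       normalization_base = 2e7) {
  t <- list(detect_per_million = detect_per_million,
            expressed_min = expressed_min,
            ratio_min = ratio_min,
            secondary_min_ratio = secondary_min_ratio,
            primary_max_ratio = primary_max_ratio,
            normalization_base = normalization_base)
  if (any(!vapply(t, function(v) is.numeric(v) && length(v) == 1 && v > 0,
                  logical(1))))
    stop("all thresholds must be single positive numbers")
  if (t$primary_max_ratio > t$secondary_min_ratio)
    stop("primary_max_ratio must not exceed secondary_min_ratio")
  class(t) <- "wall_thresholds"
  t
}

#' Normalize raw counts to reads per 20 M
#'
#' Linear library-size normalization: `raw * normalization_base / lib_size`
#' per internode.
#'
#' @param x an [internode_counts] object.
#' @param t a [thresholds] object (supplies `normalization_base`).
#' @return numeric matrix of normalized values (genes x internodes).
#' @export
normalize_counts <- function(x, t = thresholds()) {
  stopifnot(inherits(x, "internode_counts"))
  if (any(x$lib_sizes <= 0)) stop("library sizes must be positive")
  sweep(x$counts, 2, t$normalization_base / x$lib_sizes, `*`)
}

#' Split ambiguous reads between duplicated loci
#'
#' Reads mapping exactly to two duplicated genes are apportioned between the
#' two loci and the ambiguous-pair table is emptied. The default `"even"`
#' method adds half of each pair count to each gene (fractional halves are
#' permitted); `"proportional"` apportions by the two genes' unique counts at
#' that internode (falling back to an even split when both are zero). Total
#' reads per internode are conserved exactly.
#'
#' @param x an [internode_counts] object.
#' @param method `"even"` (default) or `"proportional"`.
#' @return an [internode_counts] object with updated counts and an empty
#'   ambiguous table.
#' @export
split_ambiguous <- function(x, method = c("even", "proportional")) {
  stopifnot(inherits(x, "internode_counts"))
  method <- match.arg(method)
  amb <- x$ambiguous
  counts <- x$counts
  if (nrow(amb)) {
    for (k in seq_len(nrow(amb))) {
      a <- amb$gene_a[k]; b <- amb$gene_b[k]
      i <- amb$internode[k]; n <- amb$count[k]
      if (method == "even") {
        sa <- n / 2
      } else {
        ua <- counts[a, i]; ub <- counts[b, i]
        sa <- if (ua + ub > 0) n * ua / (ua + ub) else n / 2
      }
      counts[a, i] <- counts[a, i] + sa
      counts[b, i] <- counts[b, i] + (n - sa)
    }
  }
  internode_counts(counts, x$lib_sizes, NULL)
}

#' Detection flags and expression tier for a normalized profile
#'
#' A gene is detected in an internode when its normalized value reaches the
#' detection threshold (default 20 per 20 M, i.e. one read per million). The
#' tier is `ratio_evaluable` when the sum of normalized values over the four
#' internodes reaches `ratio_min` (default 500 per 20 M, inclusive),
#' `expressed` when it reaches `expressed_min` (default 95, inclusive), and
#' `below_detection` otherwise.
#'
#' @param norm named numeric vector (`i4`, `i5`, `i6`, `i8`) or a matrix of
#'   normalized values with those columns.
#' @param t a [thresholds] object.
#' @return a data frame with columns `det_i4`..`det_i8` (logical), `total`
#'   and `tier`.
#' @export
call_expression <- function(norm, t = thresholds()) {
  m <- as_norm_matrix(norm)
  detected <- m >= t$detect_per_million * t$normalization_base / 1e6
  total <- rowSums(m)
  tier <- ifelse(total >= t$ratio_min, "ratio_evaluable",
                 ifelse(total >= t$expressed_min, "expressed",
                        "below_detection"))
  out <- data.frame(detected, total = total, tier = tier,
                    stringsAsFactors = FALSE)
  names(out)[1:4] <- paste0("det_", colnames(m))
  rownames(out) <- rownames(m)
  out
}

as_norm_matrix <- function(norm) {
  if (is.matrix(norm)) m <- norm
  else m <- matrix(norm[c("i4", "i5", "i6", "i8")], nrow = 1,
                   dimnames = list(NULL, c("i4", "i5", "i6", "i8")))
  if (!all(c("i4", "i5", "i6", "i8") %in% colnames(m)))
    stop("normalized profile must cover internodes i4, i5, i6, i8")
  m[, c("i4", "i5", "i6", "i8"), drop = FALSE]
}

#' Secondary/primary expression ratio
#'
#' The ratio of summed normalized reads in the two lower (older,
#' secondary-wall-forming) internodes to the two upper (elongating)
#' internodes: `(i4 + i5) / (i6 + i8)`. Defined only for ratio-evaluable
#' genes; calling it on a profile below the ratio threshold is a contract
#' error. A zero denominator with a positive numerator yields `Inf`
#' (logged as degenerate); 0/0 cannot occur for an evaluable gene.
#'
#' @param norm named numeric vector or matrix of normalized values.
#' @param t a [thresholds] object used to enforce the evaluability contract.
#' @return numeric vector of ratios (possibly `Inf`).
#' @export
expression_ratio <- function(norm, t = thresholds()) {
  m <- as_norm_matrix(norm)
  total <- rowSums(m)
  if (any(total < t$ratio_min))
    stop("expression_ratio called on gene(s) below the ratio-evaluation ",
         "threshold (", t$ratio_min, " per 20 M)")
  num <- m[, "i4"] + m[, "i5"]
  den <- m[, "i6"] + m[, "i8"]
  r <- ifelse(den == 0, Inf, num / den)
  if (any(den == 0))
    warning(sum(den == 0), " gene(s) with zero upper-internode signal: ",
            "ratio set to Inf")
  names(r) <- rownames(m)
  r
}

#' Classify an expression ratio
#'
#' Ratio >= 2 (including `Inf`) is `secondary`; ratio < 1 is `elongation`
#' (primary-wall association); 1 <= ratio < 2 is `transitional`. Boundaries
#' follow the quoted criteria: "2 or higher" is secondary and "<1" is
#' elongation, so ratios of exactly 1 and 2 fall to transitional and
#' secondary respectively. Cut points are configurable via [thresholds()].
#'
#' @param ratio numeric vector of defined ratios (reals or `Inf`).
#' @param t a [thresholds] object.
#' @return character vector over `{elongation, transitional, secondary}`.
#' @export
classify_ratio <- function(ratio, t = thresholds()) {
  if (any(is.na(ratio)))
    stop("classify_ratio called on undefined ratio(s)")
  if (any(ratio < 0))
    stop("ratios must be non-negative")
  ifelse(ratio >= t$secondary_min_ratio, "secondary",
         ifelse(ratio < t$primary_max_ratio, "elongation", "transitional"))
}

#' Full expression profiling chain
#'
#' Splits ambiguous reads, normalizes to reads per 20 M, applies the
#' detection / expression / ratio thresholds, and classifies ratio-evaluable
#' genes. Genes below the ratio threshold carry `ratio = NA` and class
#' `unclassified`.
#'
#' @param x an [internode_counts] object.
#' @param t a [thresholds] object.
#' @param split ambiguous-read apportionment method, see [split_ambiguous()].
#' @return data frame with one row per gene: `gene`, `n4`, `n5`, `n6`, `n8`
#'   (normalized values), `det_i4`..`det_i8`, `total`, `tier`, `ratio`,
#'   `class`.
#' @export
profile_expression <- function(x, t = thresholds(),
                               split = c("even", "proportional")) {
  split <- match.arg(split)
  xs <- split_ambiguous(x, method = split)
  norm <- normalize_counts(xs, t)
  tiers <- call_expression(norm, t)
  ratio <- rep(NA_real_, nrow(norm))
  cls <- rep("unclassified", nrow(norm))
  ev <- tiers$tier == "ratio_evaluable"
  if (any(ev)) {
    ratio[ev] <- expression_ratio(norm[ev, , drop = FALSE], t)
    cls[ev] <- classify_ratio(ratio[ev], t)
  }
  data.frame(gene = rownames(norm),
             n4 = norm[, "i4"], n5 = norm[, "i5"],
             n6 = norm[, "i6"], n8 = norm[, "i8"],
             tiers[, 1:4],
             total = tiers$total, tier = tiers$tier,
             ratio = ratio, class = cls,
             row.names = NULL, stringsAsFactors = FALSE)
}
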