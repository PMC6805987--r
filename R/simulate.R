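#' Simulation configuration
#'
#' Study conditions for the synthetic gene-family generator: families of
#' aligned protein sequences with known subgroup (clade) structure including
#' species-specific subgroups and duplicated paralog pairs, plus internode
#' count profiles with known expression class. The four internode libraries
#' mirror the profiled stem internodes 4, 5, 6 and 8 (internode 7 is never
#' generated).
#'
#' @param n_families number of gene families.
#' @param genes_per_family genes per family (across all species).
#' @param n_species number of species (default 3, emulating a maize / rice /
#'   Arabidopsis design; species 1 is the query species whose counts are
#'   simulated, the last is the reference species carrying anchors).
#' @param dup_fraction proportion in `[0, 1]` of query-species genes given a
#'   duplicated paralog partner sharing ambiguous reads.
#' @param class_mix named proportions over elongation / transitional /
#'   secondary / not_expressed, summing to 1.
#' @param lib_sizes four positive library sizes (reads per internode).
#' @param dispersion negative-binomial dispersion of counts (variance =
#'   mu + dispersion * mu^2). `0` gives the deterministic noise-free limit.
#' @param effect_size expected lower/upper ratio for secondary-class genes
#'   (reciprocal for elongation); must be >= 1.
#' @param alignment_length number of aligned residue columns.
#' @param mutation_rate per-site substitution probability per unit branch
#'   length of the guide tree, in `[0, 1)`.
#' @param ambig_fraction fraction of a duplicated gene's reads emitted as
#'   ambiguous pair counts rather than unique counts.
#' @param ortholog_concordance probability that a query gene's designated
#'   reference anchor is annotated in the concordant wall context (default
#'   0.25, the study-reported order of magnitude for secondary-wall genes).
#' @param mean_expression median of the lognormal total-expression
#'   distribution (reads per 20 M over the four internodes) for expressed
#'   genes.
#' @param species_absent_subgroup when `TRUE`, the last subgroup of each
#'   family lacks all members of the reference species (the grass-only /
#'   eudicot-only subgroup pattern).
#' @param seed integer seed; all generator randomness derives from it.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_families = 6,
                       genes_per_family = 12,
                       n_species = 3,
                       dup_fraction = 0.2,
                       class_mix = c(elongation = 0.3, transitional = 0.2,
                                     secondary = 0.3, not_expressed = 0.2),
                       lib_sizes = c(i4 = 2e7, i5 = 2e7, i6 = 2e7, i8 = 2e7),
                       dispersion = 0.05,
                       effect_size = 4,
                       alignment_length = 200,
                       mutation_rate = 0.03,
                       ambig_fraction = 0.3,
                       ortholog_concordance = 0.25,
                       mean_expression = 2000,
                       species_absent_subgroup = TRUE,
                       seed = 1L) {
  chk <- function(ok, field, why)
    if (!ok) stop("invalid sim_config field `", field, "`: ", why)
  chk(is.numeric(n_families) && n_families >= 1, "n_families",
      "must be a positive integer")
  chk(is.numeric(genes_per_family) && genes_per_family >= 3,
      "genes_per_family", "must be >= 3")
  chk(is.numeric(n_species) && n_species >= 2 && n_species <= 9,
      "n_species", "must be between 2 and 9")
  chk(is.numeric(dup_fraction) && dup_fraction >= 0 && dup_fraction <= 1,
      "dup_fraction", "must lie in [0, 1]")
  chk(is.numeric(class_mix) && length(class_mix) == 4 &&
        setequal(names(class_mix),
                 c("elongation", "transitional", "secondary",
                   "not_expressed")) &&
        all(class_mix >= 0) && abs(sum(class_mix) - 1) < 1e-9,
      "class_mix",
      "must be named proportions over the four classes summing to 1")
  chk(is.numeric(lib_sizes) && length(lib_sizes) == 4 && all(lib_sizes > 0),
      "lib_sizes", "must be 4 positive library sizes")
  chk(is.numeric(dispersion) && dispersion >= 0, "dispersion",
      "must be >= 0")
  chk(is.numeric(effect_size) && effect_size >= 1, "effect_size",
      "must be >= 1")
  chk(is.numeric(alignment_length) && alignment_length >= 10,
      "alignment_length", "must be >= 10")
  chk(is.numeric(mutation_rate) && mutation_rate >= 0 && mutation_rate < 1,
      "mutation_rate", "must lie in [0, 1)")
  chk(is.numeric(ambig_fraction) && ambig_fraction >= 0 &&
        ambig_fraction <= 1, "ambig_fraction", "must lie in [0, 1]")
  chk(is.numeric(ortholog_concordance) && ortholog_concordance >= 0 &&
        ortholog_concordance <= 1, "ortholog_concordance",
      "must lie in [0, 1]")
  chk(is.numeric(mean_expression) && mean_expression > 0, "mean_expression",
      "must be positive")
  chk(is.numeric(seed) && abs(seed) < 2^31, "seed",
      "must be a 32-bit integer")
  if (is.null(names(lib_sizes))) names(lib_sizes) <- c("i4", "i5", "i6", "i8")
  cfg <- list(n_families = as.integer(n_families),
              genes_per_family = as.integer(genes_per_family),
              n_species = as.integer(n_species),
              dup_fraction = dup_fraction,
              class_mix = class_mix[c("elongation", "transitional",
                                      "secondary", "not_expressed")],
              lib_sizes = lib_sizes[c("i4", "i5", "i6", "i8")],
              dispersion = dispersion,
              effect_size = effect_size,
              alignment_length = as.integer(alignment_length),
              mutation_rate = mutation_rate,
              ambig_fraction = ambig_fraction,
              ortholog_concordance = ortholog_concordance,
              mean_expression = mean_expression,
              species_absent_subgroup = isTRUE(species_absent_subgroup),
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

sim_species <- function(n) head(c("Zma", "Osa", "Ath",
                                  paste0("Sp", 4:9)), n)

AA20 <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")

mutate_seq <- function(seq, p) {
  if (p <= 0) return(seq)
  hit <- stats::runif(length(seq)) < p
  if (any(hit)) {
    repl <- sample(AA20, sum(hit), replace = TRUE)
    # force a change at hit sites
    same <- repl == seq[hit]
    while (any(same)) {
      repl[same] <- sample(AA20, sum(same), replace = TRUE)
      same <- repl == seq[hit]
    }
    seq[hit] <- repl
  }
  seq
}

# guide-tree node constructors (lengths are branch multipliers applied to
# mutation_rate during sequence evolution)
gt_tip <- function(id, len) list(tip = id, len = len)
gt_node <- function(children, len) list(children = children, len = len)

gt_newick <- function(node) {
  if (!is.null(node$tip))
    return(paste0(node$tip, ":", node$len))
  paste0("(", paste(vapply(node$children, gt_newick, character(1)),
                    collapse = ","), "):", node$len)
}

gt_evolve <- function(node, seq, rate, store) {
  seq2 <- mutate_seq(seq, rate * node$len)
  if (!is.null(node$tip)) {
    store[[node$tip]] <- seq2
    return(store)
  }
  for (ch in node$children) store <- gt_evolve(ch, seq2, rate, store)
  store
}

# caterpillar join of a list of subtrees with the given stem length
gt_join <- function(subtrees, len) {
  acc <- subtrees[[1]]
  for (k in seq_along(subtrees)[-1])
    acc <- gt_node(list(acc, subtrees[[k]]), len)
  acc
}

#' Generate synthetic aligned gene families with known structure
#'
#' Families are built from "units": a query-species gene (or a duplicated
#' pair of paralogs) placed as sister to a designated reference-species
#' anchor, with one gene of each intermediate species between them. Units
#' are grouped into subgroups joined by long stem branches, so subgroups
#' form recoverable clades; within-unit branches are short, so each query
#' gene's closest reference-species sequence is its designated anchor.
#' Sequences are evolved from a random root by per-site substitution along
#' the guide tree. When `species_absent_subgroup` is set, the last subgroup
#' of each family contains no reference-species gene.
#'
#' @param config a [sim_config()] object.
#' @return list with elements `alignments` (named list of named character
#'   vectors, one per family), `truth` (data frame: `gene`, `species`,
#'   `family`, `subgroup`, `class`, `partner`, `ref_gene`, `wall_context`,
#'   `is_anchor`) and `guide_trees` (named character vector of Newick
#'   strings, branch lengths = substitution multipliers).
#' @export
generate_families <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  species <- sim_species(config$n_species)
  qsp <- species[1]
  refsp <- species[config$n_species]
  mids <- setdiff(species, c(qsp, refsp))
  classes <- names(config$class_mix)

  alignments <- list(); guide <- character(0); truth <- list()
  for (f in seq_len(config$n_families)) {
    fam <- sprintf("FAM%02d", f)
    G <- config$genes_per_family
    # plan unit shapes first (no ids): each unit holds nq query genes
    # (2 = duplicated pair), one gene per intermediate species, and a
    # reference anchor unless the unit sits in the species-absent subgroup
    full <- config$n_species
    n_units_est <- max(2, ceiling(G / full))
    n_sub <- max(2, ceiling(n_units_est / 2))
    dup_pairs_left <- floor(round(config$dup_fraction * G) / 2)
    shapes <- list(); remaining <- G; u <- 0
    while (remaining > 0) {
      u <- u + 1
      sub <- (u - 1) %% n_sub + 1
      no_ref <- config$species_absent_subgroup && sub == n_sub
      dup <- dup_pairs_left > 0 && remaining >= full + 1
      if (dup) dup_pairs_left <- dup_pairs_left - 1
      nq <- if (dup) 2 else 1
      want <- c(rep(qsp, nq), if (!no_ref) refsp, mids)
      # species-absent units get an extra query gene (lineage expansion)
      if (no_ref && remaining >= length(want) + 1 && !dup)
        want <- c(want, qsp)
      take <- head(want, remaining)
      shapes[[u]] <- list(sub = sub, dup = dup && sum(take == qsp) >= 2,
                          species = take)
      remaining <- remaining - length(take)
    }
    n_units <- length(shapes)
    sub_of_unit <- vapply(shapes, function(s) as.integer(s$sub), integer(1))
    counter <- setNames(rep(0L, length(species)), species)
    gid <- function(sp) {
      counter[sp] <<- counter[sp] + 1L
      sprintf("%s_%s_%02d", fam, sp, counter[sp])
    }
    units <- lapply(shapes, function(s) {
      qs <- vapply(which(s$species == qsp), function(i) gid(qsp),
                   character(1))
      rf <- if (refsp %in% s$species) gid(refsp) else NULL
      mg <- vapply(s$species[s$species %in% mids], gid, character(1))
      list(q = qs, dup = s$dup, ref = rf, mids = unname(mg))
    })

    # guide tree: query genes as a short-branch cherry/caterpillar, then
    # intermediate species, reference anchor outermost within the unit
    unit_tree <- function(u) {
      qt <- gt_tip(u$q[1], if (length(u$q) > 1) 0.3 else 0.7)
      if (length(u$q) > 1)
        for (k in 2:length(u$q))
          qt <- gt_node(list(qt, gt_tip(u$q[k], 0.3)), 0.4)
      core <- qt
      for (mg in u$mids)
        core <- gt_node(list(core, gt_tip(mg, 1)), 0.5)
      if (!is.null(u$ref))
        core <- gt_node(list(core, gt_tip(u$ref, 1)), 0.5)
      core
    }
    subs_present <- sort(unique(sub_of_unit))
    sub_trees <- lapply(subs_present, function(s) {
      ut <- lapply(units[sub_of_unit == s], unit_tree)
      gt_join(ut, 1)
    })
    fam_tree <- gt_join(lapply(sub_trees, function(st) {
      st$len <- st$len + 3  # subgroup stem
      st
    }), 0.5)
    fam_tree$len <- 0
    guide[fam] <- paste0(gsub(":0$", "", gt_newick(fam_tree)), ";")

    root <- sample(AA20, config$alignment_length, replace = TRUE)
    seqs <- gt_evolve(fam_tree, root, config$mutation_rate, list())
    alignments[[fam]] <- vapply(seqs, paste, character(1), collapse = "")

    # ground truth rows
    for (u in seq_len(n_units)) {
      un <- units[[u]]
      sub <- sprintf("%s.SG%d", fam, sub_of_unit[u])
      cls <- sample(classes, 1, prob = config$class_mix)
      ref_ctx <- NA_character_
      if (!is.null(un$ref)) {
        concord <- stats::runif(1) < config$ortholog_concordance
        ref_ctx <- switch(cls,
          elongation = if (concord) "primary" else "secondary",
          secondary = if (concord) "secondary" else "primary",
          sample(c("primary", "secondary"), 1))
      }
      add <- function(gene, sp, class, partner, refg, ctx, anchor)
        truth[[length(truth) + 1]] <<-
          data.frame(gene = gene, species = sp, family = fam,
                     subgroup = sub, class = class, partner = partner,
                     ref_gene = refg, wall_context = ctx,
                     is_anchor = anchor, stringsAsFactors = FALSE)
      pr <- rep(NA_character_, length(un$q))
      if (isTRUE(un$dup) && length(un$q) >= 2)
        pr[1:2] <- c(un$q[2], un$q[1])
      for (k in seq_along(un$q))
        add(un$q[k], qsp, cls, pr[k],
            if (is.null(un$ref)) NA_character_ else un$ref,
            NA_character_, FALSE)
      if (!is.null(un$ref))
        add(un$ref, refsp, NA_character_, NA_character_, NA_character_,
            ref_ctx, TRUE)
      for (k in seq_along(un$mids))
        add(un$mids[k], mids[k], NA_character_, NA_character_,
            NA_character_, NA_character_, TRUE)
    }
  }
  truth <- do.call(rbind, c(truth, list(make.row.names = FALSE)))
  list(alignments = alignments, truth = truth, guide_trees = guide)
}

#' Generate internode counts with known expression class
#'
#' Per-gene expected totals (reads per 20 M summed over the four internodes)
#' are lognormal for expressed classes (floored so that the ratio-evaluation
#' threshold is met) and uniformly below the expression threshold for
#' `not_expressed` genes. The expected lower/upper ratio is `effect_size`
#' for secondary, its reciprocal for elongation, and uniform in (1, 2) for
#' transitional genes. Counts are negative-binomial around the per-internode
#' means (deterministic rounded means when `dispersion = 0`). Duplicated
#' partners share their expected total and ratio. For each duplicated gene a
#' binomial `ambig_fraction` of its reads is emitted as ambiguous pair
#' counts instead of unique counts; reads are conserved exactly by
#' construction.
#'
#' @param truth the `truth` data frame from [generate_families()].
#' @param config the same [sim_config()] object.
#' @return an [internode_counts] object, with attributes `true_totals`
#'   (matrix of simulated per-gene per-internode totals before ambiguity),
#'   `expected_ratio` and `expected_total` (named vectors).
#' @export
generate_counts <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"))
  needed <- c("gene", "species", "class", "partner")
  if (!all(needed %in% names(truth)))
    stop("`truth` must come from generate_families()")
  set.seed(config$seed + 1L)
  qsp <- sim_species(config$n_species)[1]
  q <- truth[truth$species == qsp, , drop = FALSE]
  genes <- q$gene
  n <- length(genes)

  exp_total <- numeric(n); exp_ratio <- numeric(n)
  done <- setNames(rep(FALSE, n), genes)
  for (k in seq_len(n)) {
    if (done[k]) next
    cls <- q$class[k]
    if (cls == "not_expressed") {
      tot <- stats::runif(1, 10, 80)
      r <- 1
    } else {
      tot <- max(stats::rlnorm(1, log(config$mean_expression), 0.5), 600)
      r <- switch(cls,
                  secondary = config$effect_size,
                  elongation = 1 / config$effect_size,
                  transitional = stats::runif(1, 1 + 1e-6, 2 - 1e-6))
    }
    exp_total[k] <- tot; exp_ratio[k] <- r; done[k] <- TRUE
    if (!is.na(q$partner[k])) {
      p <- match(q$partner[k], genes)
      if (!is.na(p) && !done[p]) {
        exp_total[p] <- tot; exp_ratio[p] <- r; done[p] <- TRUE
      }
    }
  }

  lib <- config$lib_sizes
  base <- 2e7
  lower <- exp_total * exp_ratio / (1 + exp_ratio)
  upper <- exp_total - lower
  mu_norm <- cbind(i4 = lower / 2, i5 = lower / 2,
                   i6 = upper / 2, i8 = upper / 2)
  mu_raw <- sweep(mu_norm, 2, lib / base, `*`)
  if (config$dispersion == 0) {
    raw <- round(mu_raw)
  } else {
    raw <- matrix(stats::rnbinom(length(mu_raw), mu = mu_raw,
                                 size = 1 / config$dispersion),
                  nrow = n, dimnames = dimnames(mu_raw))
  }
  rownames(raw) <- genes

  # ambiguous reads for duplicated pairs
  amb <- list()
  unique_counts <- raw
  pairs <- q[!is.na(q$partner) & q$gene < q$partner, c("gene", "partner")]
  if (nrow(pairs) && config$ambig_fraction > 0) {
    for (k in seq_len(nrow(pairs))) {
      a <- pairs$gene[k]; b <- pairs$partner[k]
      for (i in c("i4", "i5", "i6", "i8")) {
        ca <- raw[a, i]; cb <- raw[b, i]
        if (config$dispersion == 0) {
          aa <- round(config$ambig_fraction * ca)
          ab <- round(config$ambig_fraction * cb)
        } else {
          aa <- stats::rbinom(1, ca, config$ambig_fraction)
          ab <- stats::rbinom(1, cb, config$ambig_fraction)
        }
        unique_counts[a, i] <- ca - aa
        unique_counts[b, i] <- cb - ab
        amb[[length(amb) + 1]] <-
          data.frame(gene_a = a, gene_b = b, internode = i,
                     count = aa + ab, stringsAsFactors = FALSE)
      }
    }
  }
  amb <- if (length(amb)) do.call(rbind, amb) else NULL
  out <- internode_counts(unique_counts, lib, amb)
  attr(out, "true_totals") <- raw
  attr(out, "expected_ratio") <- setNames(exp_ratio, genes)
  attr(out, "expected_total") <- setNames(exp_total, genes)
  out
}
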