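# End-to-end orchestration: simulate fixtures, profile expression, build
# family trees, assign subgroups, call orthologs, summarize families.

# small deterministic string hash for run headers (hex, 31-bit)
config_hash <- function(...) {
  s <- paste(utils::capture.output(str(list(...))), collapse = "\n")
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", h)
}

run_meta <- function(seed, extra = character()) {
  c(paste0("stemwall ", as.character(utils::packageVersion("stemwall"))),
    paste0("date: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    paste0("seed: ", seed),
    extra)
}

#' Simulate a full fixture directory
#'
#' Writes, under `out_dir`: one aligned FASTA per family
#' (`families/<FAM>.fasta`), guide trees (`guide_trees.nwk` +
#' `guide_trees.tsv` naming them), `truth.tsv` (full ground truth),
#' `annotations.tsv` (what an analyst would have: species/family for all
#' genes, subgroup and wall-context labels for anchors only), `counts.tsv`,
#' `lib_sizes.tsv`, `ambiguous.tsv`. Deterministic for a given config.
#'
#' @param config a [sim_config()] object.
#' @param out_dir output directory.
#' @return (invisibly) list with the generated objects and `dir`.
#' @export
run_simulate <- function(config, out_dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(file.path(out_dir, "families"), showWarnings = FALSE,
             recursive = TRUE)
  fams <- generate_families(config)
  counts <- generate_counts(fams$truth, config)
  meta <- run_meta(config$seed,
                   paste0("config_hash: ", config_hash(config)))

  for (f in names(fams$alignments))
    write_alignment(fams$alignments[[f]],
                    file.path(out_dir, "families", paste0(f, ".fasta")))
  writeLines(unname(fams$guide_trees),
             file.path(out_dir, "guide_trees.nwk"))
  write_tsv(data.frame(family = names(fams$guide_trees),
                       line = seq_along(fams$guide_trees)),
            file.path(out_dir, "guide_trees.tsv"), meta)
  write_tsv(fams$truth, file.path(out_dir, "truth.tsv"), meta)
  ann <- fams$truth[, c("gene", "species", "family", "subgroup",
                        "wall_context")]
  ann$subgroup[!fams$truth$is_anchor] <- NA  # analyst does not know these
  write_tsv(ann, file.path(out_dir, "annotations.tsv"), meta)
  write_internode_counts(counts, out_dir, meta)
  invisible(list(dir = out_dir, families = fams, counts = counts))
}

#' Run the full profiling pipeline on a fixture directory
#'
#' Reads counts, library sizes, ambiguous pairs, annotations and per-family
#' alignments (layout as written by [run_simulate()]), then: splits
#' ambiguous reads, normalizes, tiers and classifies genes; builds a
#' bootstrapped neighbor-joining tree per family and assigns subgroups from
#' anchors; finds each query gene's closest reference-species homolog;
#' calls putative orthologs by shared wall context; and writes `calls.tsv`,
#' `subgroups.tsv`, `orthologs.tsv`, `summary.tsv` and `trees/<FAM>.nwk`
#' under `out_dir`. Output headers carry the seed, a config hash and the
#' threshold values; reruns on identical inputs are byte-identical except
#' for the date line.
#'
#' @param in_dir fixture directory.
#' @param out_dir output directory.
#' @param t a [thresholds()] object.
#' @param n_reps bootstrap replicates per family tree (default 1000).
#' @param min_support minimal clade support for subgroup assignment.
#' @param query_species,reference_species species labels.
#' @param seed integer seed driving the bootstrap resampling.
#' @param split ambiguous-read split method, see [split_ambiguous()].
#' @return (invisibly) list of the computed tables.
#' @export
run_profile <- function(in_dir, out_dir, t = thresholds(), n_reps = 1000,
                        min_support = 50, query_species = "Zma",
                        reference_species = "Ath", seed = 1,
                        split = c("even", "proportional")) {
  split <- match.arg(split)
  counts <- read_internode_counts(file.path(in_dir, "counts.tsv"),
                                  file.path(in_dir, "lib_sizes.tsv"),
                                  file.path(in_dir, "ambiguous.tsv"))
  ann <- read_annotations(file.path(in_dir, "annotations.tsv"))
  fasta <- sort(list.files(file.path(in_dir, "families"),
                           pattern = "\\.fasta$", full.names = TRUE))

  calls <- profile_expression(counts, t, split)

  dir.create(file.path(out_dir, "trees"), showWarnings = FALSE,
             recursive = TRUE)
  assignments <- list(); homologs <- list()
  for (k in seq_along(fasta)) {
    fam <- sub("\\.fasta$", "", basename(fasta[k]))
    aln <- read_alignment(fasta[k])
    tr <- bootstrap_support(aln, n_reps = n_reps, seed = seed + k)
    write_tree(tr, file.path(out_dir, "trees", paste0(fam, ".nwk")))
    anchors <- ann[!is.na(ann$subgroup) & ann$gene %in% names(aln), ]
    if (nrow(anchors)) {
      asg <- assign_subgroups(tr, anchors, min_support)
      asg$family <- fam
      assignments[[fam]] <- asg
    }
    hom <- closest_homologs(aln, ann, query_species, reference_species)
    if (nrow(hom)) homologs[[fam]] <- hom
  }
  assignments <- do.call(rbind, c(assignments, list(make.row.names = FALSE)))
  homologs <- do.call(rbind, c(homologs, list(make.row.names = FALSE)))

  ortho <- call_orthologs(calls, homologs, ann)
  qann <- ann[ann$species == query_species, , drop = FALSE]
  summ <- summarize_all(calls, qann)

  meta <- run_meta(seed, c(
    paste0("config_hash: ", config_hash(t, n_reps, min_support,
                                        query_species, reference_species,
                                        seed, split)),
    paste0("thresholds: detect=", t$detect_per_million,
           "/M expressed>=", t$expressed_min,
           " ratio>=", t$ratio_min,
           " secondary>=", t$secondary_min_ratio,
           " elongation<", t$primary_max_ratio,
           " base=", t$normalization_base)))
  write_tsv(calls, file.path(out_dir, "calls.tsv"), meta)
  write_tsv(assignments, file.path(out_dir, "subgroups.tsv"), meta)
  write_tsv(ortho, file.path(out_dir, "orthologs.tsv"), meta)
  write_tsv(summ, file.path(out_dir, "summary.tsv"), meta)
  invisible(list(calls = calls, subgroups = assignments,
                 orthologs = ortho, summary = summ))
}

#' Validate a fixture directory
#'
#' Non-fatal aggregated checks of the TSV schemas, the internode set
#' (exactly i4, i5, i6, i8), gene-id uniqueness, ambiguous-pair references,
#' counts/annotations consistency, and per-family alignment regularity.
#'
#' @param in_dir fixture directory.
#' @return data frame with columns `level` (`error` / `warning`) and
#'   `message`; zero rows when the fixture is clean.
#' @export
validate_inputs <- function(in_dir) {
  probs <- list()
  note <- function(level, msg)
    probs[[length(probs) + 1]] <<- data.frame(level = level, message = msg,
                                              stringsAsFactors = FALSE)
  cpath <- file.path(in_dir, "counts.tsv")
  lpath <- file.path(in_dir, "lib_sizes.tsv")
  apath <- file.path(in_dir, "ambiguous.tsv")
  npath <- file.path(in_dir, "annotations.tsv")
  for (p in c(cpath, lpath, npath))
    if (!file.exists(p)) note("error", paste0("missing file: ", p))
  genes <- character(0)
  if (file.exists(cpath)) {
    cts <- read_tsv(cpath)
    if (!"gene" %in% names(cts)) note("error", "counts.tsv: no gene column")
    else {
      if (anyDuplicated(cts$gene))
        note("error", paste0("counts.tsv: duplicated gene id(s): ",
                             paste(unique(cts$gene[duplicated(cts$gene)]),
                                   collapse = ", ")))
      genes <- as.character(cts$gene)
    }
    have <- setdiff(names(cts), "gene")
    extra <- setdiff(have, c("i4", "i5", "i6", "i8"))
    if (length(extra))
      note("error", paste0("counts.tsv: internode column(s) not allowed: ",
                           paste(extra, collapse = ", ")))
    miss <- setdiff(c("i4", "i5", "i6", "i8"), have)
    if (length(miss))
      note("error", paste0("counts.tsv: missing internode column(s): ",
                           paste(miss, collapse = ", ")))
    num <- cts[, intersect(have, c("i4", "i5", "i6", "i8")), drop = FALSE]
    if (length(num) && any(unlist(num) < 0, na.rm = TRUE))
      note("error", "counts.tsv: negative counts")
  }
  if (file.exists(lpath)) {
    libs <- read_tsv(lpath)
    if (!all(c("internode", "lib_size") %in% names(libs)))
      note("error", "lib_sizes.tsv: needs columns internode, lib_size")
    else if (any(libs$lib_size <= 0))
      note("error", "lib_sizes.tsv: non-positive library size")
  }
  if (file.exists(apath)) {
    amb <- read_tsv(apath)
    if (nrow(amb)) {
      if (!all(c("gene_a", "gene_b", "internode", "count") %in% names(amb)))
        note("error",
             "ambiguous.tsv: needs columns gene_a, gene_b, internode, count")
      else {
        unknown <- setdiff(unique(c(amb$gene_a, amb$gene_b)), genes)
        if (length(unknown))
          note("error", paste0("ambiguous.tsv: unknown gene(s): ",
                               paste(unknown, collapse = ", ")))
        if (any(amb$gene_a == amb$gene_b))
          note("error", "ambiguous.tsv: pair with gene_a == gene_b")
      }
    }
  }
  ann_genes <- character(0)
  if (file.exists(npath)) {
    ann <- tryCatch(read_annotations(npath), error = function(e) {
      note("error", conditionMessage(e)); NULL
    })
    if (!is.null(ann)) ann_genes <- ann$gene
  }
  if (length(genes) && length(ann_genes)) {
    orphan <- setdiff(genes, ann_genes)
    if (length(orphan))
      note("warning", paste0("gene(s) in counts but not annotations: ",
                             paste(orphan, collapse = ", ")))
  }
  fdir <- file.path(in_dir, "families")
  if (dir.exists(fdir)) {
    for (fa in list.files(fdir, pattern = "\\.fasta$", full.names = TRUE)) {
      ok <- tryCatch({ read_alignment(fa); TRUE },
                     error = function(e) { note("error",
                       conditionMessage(e)); FALSE })
      invisible(ok)
    }
  }
  if (length(probs) == 0)
    return(data.frame(level = character(), message = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, c(probs, list(make.row.names = FALSE)))
}
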