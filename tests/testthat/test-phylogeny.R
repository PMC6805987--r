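test_that("p-distance follows pairwise-deletion arithmetic", {
  aln <- c(s1 = "AAAA", s2 = "AAAA", s3 = "AAAT", s4 = "AA--", s5 = "AAGG")
  d <- p_distance(aln)
  expect_equal(d["s1", "s2"], 0)
  expect_equal(d["s1", "s3"], 0.25)   # 1 mismatch / 4 sites
  expect_equal(d["s4", "s5"], 0)      # 2 comparable sites, 0 mismatches
  expect_true(isSymmetric(d))
  expect_equal(diag(d), setNames(rep(0, 5), names(aln)))
  expect_true(all(d >= 0 & d <= 1))
})

test_that("p-distance rejects ragged alignments and flags gap-only pairs", {
  expect_error(p_distance(c(a = "AAA", b = "AAAA")), "ragged")
  expect_warning(d <- p_distance(c(a = "AA--", b = "--AA")),
                 "no comparable")
  expect_equal(d["a", "b"], 1)
})

test_that("3-taxon NJ reduces to the closed-form star", {
  d <- matrix(c(0, 0.3, 0.5,
                0.3, 0, 0.6,
                0.5, 0.6, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(d)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[["a"]], (0.3 + 0.5 - 0.6) / 2)
  expect_equal(bl[["b"]], (0.3 + 0.6 - 0.5) / 2)
  expect_equal(bl[["c"]], (0.5 + 0.6 - 0.3) / 2)
  expect_error(nj_tree(d[1:2, 1:2]), "at least 3")
})

test_that("NJ exactly recovers additive trees (topology and path lengths)", {
  set.seed(101)
  for (k in 1:30) {
    fx <- random_additive(8)
    est <- nj_tree(fx$d)
    expect_equal(ape::dist.topo(ape::unroot(fx$tree), ape::unroot(est)), 0,
                 ignore_attr = TRUE)
    De <- ape::cophenetic.phylo(est)[rownames(fx$d), colnames(fx$d)]
    expect_lt(max(abs(De - fx$d)), 1e-10)
  }
})

test_that("NJ agrees with an independent implementation on noisy distances", {
  cfg <- sim_config(n_families = 1, genes_per_family = 10,
                    mutation_rate = 0.05, alignment_length = 300, seed = 21)
  fam <- generate_families(cfg)
  d <- p_distance(fam$alignments[[1]])
  ours <- nj_tree(d)
  theirs <- ape::nj(d)
  expect_equal(ape::dist.topo(ape::unroot(ours), ape::unroot(theirs)), 0,
               ignore_attr = TRUE)
})

test_that("negative branch estimates are clamped to non-negative lengths", {
  # triangle-inequality violation: raw closed-form estimate for c is -0.05
  d <- matrix(c(0, 0.5, 0.3,
                0.5, 0, 0.1,
                0.3, 0.1, 0), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  tr <- nj_tree(d)
  expect_true(all(tr$edge.length >= 0))
  # and on a larger perturbed matrix
  set.seed(8)
  fx <- random_additive(7)
  noisy <- fx$d + matrix(runif(49, 0, 0.2), 7, 7)
  noisy <- (noisy + t(noisy)) / 2; diag(noisy) <- 0
  expect_true(all(nj_tree(noisy)$edge.length >= 0))
})

test_that("congruent alignments give full bootstrap support", {
  aln <- congruent_alignment()
  tr <- bootstrap_support(aln, n_reps = 100, seed = 42)
  internal <- tr$node.label[-1]          # basal trifurcation carries NA
  expect_true(all(internal == 100))
  expect_true(all(is.na(tr$node.label[1])))
  # replicate-exact determinism under the same seed
  tr2 <- bootstrap_support(aln, n_reps = 100, seed = 42)
  expect_identical(tr$node.label, tr2$node.label)
  expect_identical(ape::write.tree(tr), ape::write.tree(tr2))
  # the conventional default depth is 1000 replicates
  expect_equal(formals(bootstrap_support)$n_reps, 1000)
})

test_that("column duplication cannot erode a fully supported edge", {
  aln <- congruent_alignment()
  dup <- vapply(aln, function(s) paste(rep(s, 3), collapse = ""),
                character(1))
  tr <- bootstrap_support(dup, n_reps = 50, seed = 7)
  expect_true(all(tr$node.label[-1] == 100))
})

test_that("supports lie in [0, 100] on noisy alignments", {
  cfg <- sim_config(n_families = 1, genes_per_family = 9,
                    mutation_rate = 0.02, alignment_length = 80, seed = 5)
  fam <- generate_families(cfg)
  tr <- bootstrap_support(fam$alignments[[1]], n_reps = 50, seed = 9)
  s <- tr$node.label[-1]
  expect_true(all(s >= 0 & s <= 100))
})

test_that("subgroup assignment follows the smallest anchored clade", {
  txt <- "((g1:1,a1:1)98:1,(g2:1,(a2:1,a3:1)90:1)95:1);"
  tr <- ape::read.tree(text = txt)
  anchors <- data.frame(gene = c("a1", "a2", "a3"),
                        subgroup = c("CesA", "CslF", "CslH"),
                        stringsAsFactors = FALSE)
  asg <- assign_subgroups(tr, anchors, min_support = 50)
  get <- function(g, col) asg[[col]][asg$gene == g]
  expect_equal(get("g1", "subgroup"), "CesA")   # sister to a single anchor
  expect_equal(get("g1", "support"), 98)
  expect_equal(get("g2", "subgroup"), "unassigned")  # mixed-label clade
  # anchors keep their own labels
  expect_equal(get("a2", "subgroup"), "CslF")
  # support gating
  strict <- assign_subgroups(tr, anchors, min_support = 99)
  expect_equal(strict$subgroup[strict$gene == "g1"], "unassigned")
  # every gene gets exactly one label or unassigned
  expect_equal(nrow(asg), length(tr$tip.label))
  expect_false(any(is.na(asg$subgroup)))
  # missing anchors are an input error listing the ids
  bad <- rbind(anchors, data.frame(gene = "zz", subgroup = "X"))
  expect_error(assign_subgroups(tr, bad), "zz")
})

test_that("zero-length edges are treated as unsupported polytomies", {
  cfg <- sim_config(n_families = 1, genes_per_family = 8,
                    mutation_rate = 0, seed = 2)
  fam <- generate_families(cfg)
  aln <- fam$alignments[[1]]
  expect_length(unique(aln), 1)  # identical sequences within the family
  tr <- bootstrap_support(aln, n_reps = 25, seed = 1)
  anchors <- fam$truth[fam$truth$is_anchor, c("gene", "subgroup")]
  asg <- assign_subgroups(tr, anchors, min_support = 50)
  expect_true(all(asg$subgroup[!asg$is_anchor] == "unassigned"))
})

test_that("closest homolog maximizes identity with lexicographic ties", {
  aln <- c(q = "AAAAAAAAAA", AT2 = "AAAAAAAAAA", AT1 = "AAAAAAAAAA",
           AT3 = "CCCCCCCCCC")
  ann <- data.frame(gene = names(aln),
                    species = c("Zma", "Ath", "Ath", "Ath"),
                    stringsAsFactors = FALSE)
  expect_warning(h <- closest_homolog("q", aln, ann, "Ath"), "equidistant")
  expect_equal(h$ref_gene, "AT1")
  expect_equal(h$identity, 1.0)
  noref <- ann; noref$species <- "Zma"
  expect_error(closest_homolog("q", aln, noref, "Ath"), "no Ath")
})

test_that("designated reference anchors are recovered as closest homologs", {
  cfg <- sim_config(n_families = 4, genes_per_family = 20,
                    alignment_length = 400, mutation_rate = 0.05, seed = 3)
  fam <- generate_families(cfg)
  truth <- fam$truth
  hit <- 0; tot <- 0
  for (f in names(fam$alignments)) {
    tq <- truth[truth$family == f & truth$species == "Zma" &
                  !is.na(truth$ref_gene), ]
    hm <- suppressWarnings(
      closest_homologs(fam$alignments[[f]], truth, "Zma", "Ath"))
    hm <- merge(hm, tq[, c("gene", "ref_gene")], by = "gene")
    tot <- tot + nrow(hm)
    hit <- hit + sum(hm$ref_gene.x == hm$ref_gene.y)
  }
  expect_gte(hit / tot, 0.99)
})
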