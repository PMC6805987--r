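test_that("normalization is linear in counts and library size", {
  x <- make_counts(g = c("g1", "g2"),
                   m = rbind(c(20, 0, 100, 40), c(0, 0, 0, 0)),
                   lib = c(i4 = 2e7, i5 = 2e7, i6 = 4e7, i8 = 2e7))
  n <- normalize_counts(x)
  expect_equal(n["g1", "i4"], 20)   # 20 reads in 20 M = 1 per million
  expect_equal(n["g1", "i6"], 50)   # 100 reads in 40 M = 50 per 20 M
  expect_equal(n["g2", ], setNames(rep(0, 4), colnames(n)))
})

test_that("normalization is scale-equivariant", {
  x <- make_counts()
  k <- 3.5
  xk <- internode_counts(x$counts * k, x$lib_sizes * k)
  expect_equal(normalize_counts(x), normalize_counts(xk))
})

test_that("ambiguous reads split evenly with totals conserved", {
  amb <- data.frame(gene_a = "gA", gene_b = "gB", internode = "i4",
                    count = 20)
  x <- make_counts(m = rbind(c(10, 0, 0, 0), c(30, 0, 0, 0)), amb = amb)
  s <- split_ambiguous(x)
  expect_equal(s$counts["gA", "i4"], 20)
  expect_equal(s$counts["gB", "i4"], 40)
  expect_equal(sum(s$counts[, "i4"]), 60)
  expect_equal(nrow(s$ambiguous), 0)
  # odd counts give fractional halves
  amb5 <- data.frame(gene_a = "gA", gene_b = "gB", internode = "i6",
                     count = 5)
  s5 <- split_ambiguous(make_counts(amb = amb5))
  expect_equal(s5$counts["gA", "i6"], 12.5)   # 10 + 2.5
  expect_equal(s5$counts["gB", "i6"], 32.5)   # 30 + 2.5
  # zero ambiguous count is a no-op
  amb0 <- data.frame(gene_a = "gA", gene_b = "gB", internode = "i4",
                     count = 0)
  s0 <- split_ambiguous(make_counts(amb = amb0))
  expect_equal(s0$counts, make_counts()$counts)
})

test_that("proportional splitting apportions by unique counts", {
  amb <- data.frame(gene_a = "gA", gene_b = "gB", internode = "i4",
                    count = 20)
  x <- make_counts(m = rbind(c(10, 0, 0, 0), c(30, 0, 0, 0)), amb = amb)
  s <- split_ambiguous(x, method = "proportional")
  expect_equal(s$counts["gA", "i4"], 15)
  expect_equal(s$counts["gB", "i4"], 45)
  # both-zero unique counts fall back to the even split
  x0 <- make_counts(m = rbind(c(0, 0, 0, 0), c(0, 0, 0, 0)), amb = amb)
  s0 <- split_ambiguous(x0, method = "proportional")
  expect_equal(s0$counts["gA", "i4"], 10)
})

test_that("ambiguous pairs referencing unknown genes are rejected", {
  amb <- data.frame(gene_a = "gA", gene_b = "nope", internode = "i4",
                    count = 1)
  expect_error(make_counts(amb = amb), "nope")
  selfp <- data.frame(gene_a = "gA", gene_b = "gA", internode = "i4",
                      count = 1)
  expect_error(make_counts(amb = selfp), "gene_a == gene_b")
})

test_that("splitting conserves per-internode totals on random fixtures", {
  set.seed(77)
  for (k in 1:200) {
    x <- random_counts(n_genes = sample(4:10, 1), n_pairs = sample(0:3, 1))
    before <- colSums(x$counts) +
      vapply(c("i4", "i5", "i6", "i8"), function(i)
        sum(x$ambiguous$count[x$ambiguous$internode == i]), numeric(1))
    for (m in c("even", "proportional")) {
      s <- split_ambiguous(x, method = m)
      expect_lt(max(abs(colSums(s$counts) - before)), 1e-9)
    }
  }
})

test_that("expression tiers have inclusive boundaries at 95 and 500", {
  lib <- c(i4 = 2e7, i5 = 2e7, i6 = 2e7, i8 = 2e7)
  mk <- function(total) {
    m <- matrix(total / 4, 1, 4,
                dimnames = list("g", c("i4", "i5", "i6", "i8")))
    normalize_counts(internode_counts(m, lib))
  }
  expect_equal(call_expression(mk(94.9))$tier, "below_detection")
  expect_equal(call_expression(mk(95))$tier, "expressed")
  expect_equal(call_expression(mk(499.9))$tier, "expressed")
  expect_equal(call_expression(mk(500))$tier, "ratio_evaluable")
})

test_that("per-internode detection uses one read per million", {
  lib <- c(i4 = 2e7, i5 = 2e7, i6 = 2e7, i8 = 2e7)
  m <- matrix(c(20, 19, 0, 1000), 1, 4,
              dimnames = list("g", c("i4", "i5", "i6", "i8")))
  det <- call_expression(normalize_counts(internode_counts(m, lib)))
  expect_true(det$det_i4)      # exactly 20 per 20 M: detected (inclusive)
  expect_false(det$det_i5)     # 19 per 20 M: not detected
  expect_false(det$det_i6)
  expect_true(det$det_i8)
})

test_that("expression ratio is (i4+i5)/(i6+i8) with Inf degeneracy", {
  r1 <- expression_ratio(c(i4 = 300, i5 = 300, i6 = 200, i8 = 100))
  expect_equal(unname(r1), 2)
  r2 <- expression_ratio(c(i4 = 200, i5 = 200, i6 = 200, i8 = 200))
  expect_equal(unname(r2), 1)
  expect_warning(
    r3 <- expression_ratio(c(i4 = 300, i5 = 300, i6 = 0, i8 = 0)),
    "Inf")
  expect_equal(unname(r3), Inf)
  # contract: not defined below the ratio-evaluation threshold
  expect_error(expression_ratio(c(i4 = 50, i5 = 50, i6 = 50, i8 = 50)),
               "below the ratio-evaluation threshold")
})

test_that("ratio classes use the quoted inclusive/exclusive boundaries", {
  expect_equal(classify_ratio(2.0), "secondary")
  expect_equal(classify_ratio(0.5), "elongation")
  expect_equal(classify_ratio(1.0), "transitional")
  expect_equal(classify_ratio(1.999), "transitional")
  expect_equal(classify_ratio(0.999), "elongation")
  expect_equal(classify_ratio(Inf), "secondary")
  expect_error(classify_ratio(NA_real_), "undefined")
})

test_that("classification is total and monotone over [0, Inf]", {
  r <- sort(c(runif(50, 0, 5), 0, 1, 2, Inf))
  cls <- classify_ratio(r)
  expect_true(all(cls %in% c("elongation", "transitional", "secondary")))
  lev <- match(cls, c("elongation", "transitional", "secondary"))
  expect_true(all(diff(lev) >= 0))
})

test_that("profile_expression ties ratio and class to the evaluable tier", {
  lib <- c(i4 = 2e7, i5 = 2e7, i6 = 2e7, i8 = 2e7)
  m <- rbind(ev = c(400, 400, 100, 100),   # evaluable, ratio 4
             lo = c(30, 30, 30, 30),       # expressed, not evaluable
             off = c(5, 5, 5, 5))          # below detection
  colnames(m) <- c("i4", "i5", "i6", "i8")
  calls <- profile_expression(internode_counts(m, lib))
  expect_equal(calls$tier, c("ratio_evaluable", "expressed",
                             "below_detection"))
  expect_equal(calls$class, c("secondary", "unclassified", "unclassified"))
  expect_equal(calls$ratio, c(4, NA, NA))
})
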