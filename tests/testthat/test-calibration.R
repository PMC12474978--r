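test_that("youden cutpoint reproduces hand-scanned examples", {
  cp <- youden_cutpoint(c(0.9, 0.8), c(0.2, 0.1), "higher_pathogenic")
  expect_equal(cp$threshold, 0.8)
  expect_equal(cp$objective, 2.0)

  cp2 <- youden_cutpoint(c(0.9, 0.6), c(0.7, 0.1), "higher_pathogenic")
  expect_equal(sort(cp2$candidate_maxima), c(0.6, 0.9))
  expect_equal(cp2$threshold, 0.75)

  # uninformative scores: objective 1 everywhere, threshold = median
  cp3 <- youden_cutpoint(c(0.1, 0.5, 0.9), c(0.1, 0.5, 0.9),
                         "higher_pathogenic")
  expect_equal(cp3$objective, 1.0)
  expect_equal(length(cp3$candidate_maxima), 3)
  expect_equal(cp3$threshold, 0.5)

  expect_error(youden_cutpoint(numeric(0), c(1)), "non-empty")
})

test_that("youden cutpoint matches exhaustive scan on random inputs", {
  set.seed(101)
  for (i in 1:60) {
    pos <- round(runif(sample(2:40, 1)), 2)
    neg <- round(runif(sample(2:40, 1)), 2)
    for (orient in c("higher_pathogenic", "lower_pathogenic")) {
      got <- youden_cutpoint(pos, neg, orient)
      ref <- oracle_cutpoint(pos, neg, orient == "higher_pathogenic")
      expect_equal(got$threshold, ref$threshold)
      expect_equal(got$objective, ref$objective)
      expect_equal(sort(got$candidate_maxima), sort(ref$maxima))
    }
  }
})

test_that("best built-in class maximizes AUROC with fewest exclusions", {
  cs <- list(A = list(pos = c(0.9, 0.8), neg = c(0.2, 0.1)),
             B = list(pos = c(0.9, 0.3), neg = c(0.6, 0.1)))
  expect_equal(select_best_class(cs), "A")
  expect_equal(select_best_class(cs["B"]), "B")
  # identical AUROC: the class retaining more variants wins
  cs2 <- list(small = list(pos = c(0.9), neg = c(0.1)),
              big = list(pos = c(0.9, 0.8, 0.7), neg = c(0.3, 0.2, 0.1)))
  expect_equal(select_best_class(cs2), "big")
})

test_that("BH adjustment matches hand computation and reference", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04, 0.05)),
               c(0.04, 0.04, 0.05, 0.05))
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_adjust(numeric(0)), numeric(0))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(7)
  for (i in 1:50) {
    p <- runif(sample(1:30, 1))
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("q-value classification is boundary-inclusive at alpha", {
  got <- qvalue_classify(c(v1 = 0.001, v2 = 0.5))
  expect_equal(unname(got), c("pathogenic", "benign"))
  expect_equal(names(got), c("v1", "v2"))
  expect_equal(unname(qvalue_classify(c(v = 1))), "benign")
  # single p = 0.05 -> q = 0.05 -> pathogenic (q <= alpha)
  expect_equal(unname(qvalue_classify(c(v = 0.05))), "pathogenic")
})

test_that("threshold classification is boundary-inclusive per orientation", {
  hi <- method_spec("m", "higher_pathogenic", "learned_cutoff",
                    threshold = 0.5)
  got <- classify_variants(c(a = 0.5, b = 0.49, c = NA), hi)
  expect_equal(unname(got), c("pathogenic", "benign", "missing"))

  lo <- method_spec("m", "lower_pathogenic", "learned_cutoff",
                    threshold = -5)
  got2 <- classify_variants(c(a = -5.0, b = -4.9), lo)
  expect_equal(unname(got2), c("pathogenic", "benign"))

  expect_error(classify_variants(c(a = 1), method_spec("m")), "cutpoint")

  bi <- method_spec("m", calibration_mode = "builtin_classes",
                    class_map = c(D = "pathogenic", N = "benign",
                                  P = "uncertain"))
  got3 <- classify_variants(c(a = "D", b = "P", d = NA), bi)
  expect_equal(unname(got3), c("pathogenic", "uncertain", "missing"))
})

test_that("negating scores and flipping orientation leaves calls invariant", {
  set.seed(21)
  pos <- rnorm(30); neg <- rnorm(30, -1)
  s <- c(rnorm(20), NA)
  names(s) <- paste0("v", 1:21)
  cp_hi <- youden_cutpoint(pos, neg, "higher_pathogenic")
  cp_lo <- youden_cutpoint(-pos, -neg, "lower_pathogenic")
  expect_equal(cp_lo$threshold, -cp_hi$threshold)
  hi <- classify_variants(s, method_spec("m", "higher_pathogenic"), cp_hi)
  lo <- classify_variants(-s, method_spec("m", "lower_pathogenic"), cp_lo)
  expect_identical(hi, lo)
})
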