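test_that("instance multisets follow the counting level", {
  mut <- data.frame(patient_id = c("P1", "P2", "P3"), sample_id = "S",
                    gene = "KRAS", protein_change = "p.G12D",
                    chrom = NA, pos = NA, ref = NA, alt = NA,
                    context3 = NA, is_missense = TRUE,
                    oncokb_class = "oncogenic")
  expect_equal(length(build_instances(mut, "population")), 3)
  expect_equal(length(build_instances(mut, "mutation")), 1)
  expect_equal(length(build_instances(mut[0, ], "mutation")), 0)
})

test_that("negative upsampling is with replacement and reproducible", {
  u1 <- upsample_negatives(c("a", "b"), 4, seed = 9)
  expect_equal(length(u1), 4)
  expect_true(all(u1 %in% c("a", "b")))
  expect_identical(u1, upsample_negatives(c("a", "b"), 4, seed = 9))
  expect_error(upsample_negatives(character(0), 3), "empty")
})

test_that("AUROC matches hand-counted pairs and brute force", {
  expect_equal(auroc_delong(c(0.9, 0.8), c(0.2, 0.1))$auroc, 1.0)
  expect_equal(auroc_delong(c(0.9, 0.8), c(0.85, 0.2))$auroc, 0.75)
  expect_equal(auroc_delong(c(1, 2, 3), c(1, 2, 3))$auroc, 0.5)
  expect_error(auroc_delong(numeric(0), 1), "non-empty")
  set.seed(31)
  for (i in 1:100) {
    pos <- sample(0:20, sample(2:30, 1), replace = TRUE)  # ties frequent
    neg <- sample(0:20, sample(2:30, 1), replace = TRUE)
    expect_equal(auroc_delong(pos, neg)$auroc, oracle_auc(pos, neg))
  }
})

test_that("DeLong CI and paired test agree with pROC", {
  skip_if_not_installed("pROC")
  set.seed(41)
  for (i in 1:10) {
    pos <- rnorm(40, 1); neg <- rnorm(50)
    r <- auroc_delong(pos, neg)
    pr <- pROC::roc(c(rep(1, 40), rep(0, 50)), c(pos, neg), quiet = TRUE)
    ci <- as.numeric(pROC::ci.auc(pr, method = "delong"))
    expect_equal(r$auroc, as.numeric(pROC::auc(pr)))
    expect_equal(c(r$ci_low, r$ci_high), ci[c(1, 3)], tolerance = 1e-8)
  }
  pos_b <- rnorm(40, 0.5); neg_b <- rnorm(50)
  pos_a <- rnorm(40, 1); neg_a <- rnorm(50)
  dt <- delong_test(pos_a, neg_a, pos_b, neg_b)
  pr_t <- pROC::roc.test(
    pROC::roc(c(rep(1, 40), rep(0, 50)), c(pos_a, neg_a), quiet = TRUE),
    pROC::roc(c(rep(1, 40), rep(0, 50)), c(pos_b, neg_b), quiet = TRUE),
    method = "delong", paired = TRUE)
  expect_equal(dt$p, pr_t$p.value, tolerance = 1e-8)
})

test_that("identical scores give delta 0 with p = 1", {
  pos <- rnorm(20); neg <- rnorm(20)
  dt <- delong_test(pos, neg, pos, neg)
  expect_equal(dt$delta_auc, 0)
  expect_equal(dt$p, 1)
  expect_true(dt$degenerate)
  expect_error(delong_test(pos, neg, pos[-1], neg[-1]), "differ")
})

test_that("a perfect method beats a random one at q < 0.05", {
  set.seed(53)
  n <- 100
  pos <- cbind(perfect = rnorm(n, 5, 0.1), random = runif(n))
  neg <- cbind(perfect = rnorm(n, 0, 0.1), random = runif(n))
  cmp <- compare_methods(pos, neg)
  row <- cmp[cmp$method_b == "random", ]
  expect_lt(row$q, 0.05)
  expect_gt(row$delta_auc, 0.3)
})

test_that("DeLong p-values are calibrated under the null", {
  set.seed(67)
  ps <- replicate(400, {
    pos <- cbind(a = rnorm(40), b = rnorm(40))
    neg <- cbind(a = rnorm(40), b = rnorm(40))
    delong_test(pos[, "a"], neg[, "a"], pos[, "b"], neg[, "b"])$p
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("per-gene TPR counts classified truth positives", {
  cls <- c(k1 = "pathogenic", k2 = "pathogenic", k3 = "benign",
           k4 = "pathogenic", k5 = "missing", k6 = "missing")
  genes <- c(k1 = "A", k2 = "A", k3 = "A", k4 = "A", k5 = "B", k6 = "B")
  got <- suppressWarnings(
    per_gene_tpr(cls, c("k1", "k2", "k3", "k4", "k5", "k6"), genes))
  expect_equal(got$tpr[got$gene == "A"], 0.75)
  expect_equal(got$n[got$gene == "A"], 4)
  expect_false("B" %in% got$gene)  # all-missing gene omitted
  expect_warning(per_gene_tpr(cls, c("k5", "k6"), genes), "omitted")
})

test_that("class-balance upsampling leaves AUROC unchanged in expectation", {
  set.seed(71)
  pos <- rnorm(300, 1); neg <- rnorm(600)
  base <- auroc_delong(pos, neg)$auroc
  up <- replicate(200, {
    idx <- upsample_negatives(seq_along(neg), length(pos),
                              seed = sample.int(1e6, 1))
    auroc_delong(pos, neg[idx])$auroc
  })
  expect_lt(abs(mean(up) - base), 0.01)
})
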