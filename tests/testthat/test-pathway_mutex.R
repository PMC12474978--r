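mutex_fixture <- function() {
  # 8 patients: 2 gene-pathogenic & pathway-driver-free, 1 gene-pathogenic
  # & pathway-oncogenic, 3 pathway-oncogenic only, 2 neither
  pts <- data.frame(patient_id = paste0("P", 1:8), panel_id = "panel_A")
  mut <- data.frame(
    patient_id = c("P1", "P2", "P3", "P3", "P4", "P5", "P6"),
    sample_id = "S",
    gene = c("KEAP1", "KEAP1", "KEAP1", "NFE2L2", "KEAP1", "NFE2L2",
             "CUL3"),
    protein_change = c("p.A1V", "p.A1V", "p.A1V", "p.B2C", "p.D4E",
                       "p.B2C", "p.F6G"),
    chrom = NA, pos = NA, ref = NA, alt = NA, context3 = NA,
    is_missense = TRUE,
    oncokb_class = c("vus", "vus", "vus", "oncogenic", "oncogenic",
                     "oncogenic", "oncogenic"))
  cls <- c("KEAP1:p.A1V" = "pathogenic")
  list(pts = pts, mut = mut, cls = cls,
       pw = c("KEAP1", "NFE2L2", "CUL3"))
}

test_that("mutual exclusivity table matches the hand-counted fixture", {
  fx <- mutex_fixture()
  tab <- build_mutex_table("KEAP1", fx$pw, fx$cls, fx$pts, fx$mut)
  expect_equal(unname(tab), matrix(c(1, 2, 3, 2), 2, byrow = TRUE))
  expect_error(build_mutex_table("EGFR", fx$pw, fx$cls, fx$pts, fx$mut),
               "not in the pathway")
  # no pathogenic carriers: first row all zero
  tab0 <- build_mutex_table("CUL3", fx$pw, fx$cls, fx$pts, fx$mut)
  expect_equal(unname(tab0[1, ]), c(0, 0))
  # single-gene pathway: column reduces to that gene's oncogenic carriers
  tab1 <- build_mutex_table("KEAP1", "KEAP1", fx$cls, fx$pts, fx$mut)
  expect_equal(sum(tab1[, 1]), 1)  # only P4 is KEAP1-oncogenic
})

test_that("mutex Fisher applies the enumeration p and sign rule", {
  r <- mutex_fisher(matrix(c(0, 5, 5, 0), 2, byrow = TRUE))
  expect_equal(r$p, 2 / 252)
  expect_lt(r$log_or, 0)
  expect_true(r$significant)
  r2 <- mutex_fisher(matrix(c(10, 10, 10, 10), 2, byrow = TRUE))
  expect_equal(r2$log_or, 0)
  expect_false(r2$significant)
  # co-occurrence (logOR > 0) is never "mutually exclusive"
  r3 <- mutex_fisher(matrix(c(5, 0, 0, 5), 2, byrow = TRUE))
  expect_gt(r3$log_or, 0)
  expect_false(r3$significant)
  expect_null(quiet(mutex_fisher(matrix(c(0, 0, 5, 5), 2, byrow = TRUE))))
})

test_that("pathway rate divides by all pathway genes and is monotone", {
  res <- data.frame(pathway = "NRF2", significant = c(TRUE, TRUE, FALSE))
  expect_equal(pathway_rate(res, "NRF2", paste0("G", 1:10)), 0.2)
  expect_equal(pathway_rate(res[res$significant, ], "NRF2",
                            paste0("G", 1:3)), 2 / 3)
  res$significant <- FALSE
  expect_equal(pathway_rate(res, "NRF2", paste0("G", 1:10)), 0)
  res$significant <- TRUE
  expect_equal(pathway_rate(res, "NRF2", paste0("G", 1:3)), 1)
})

test_that("OR_mutex contrasts carrier classes excluding the focal gene", {
  pts <- data.frame(patient_id = paste0("P", 1:20), panel_id = "panel_A")
  mut <- do.call(rbind, lapply(1:20, function(i) {
    rows <- data.frame(patient_id = paste0("P", i), sample_id = "S",
                       gene = "KEAP1",
                       protein_change = if (i <= 10) "p.A1V" else "p.C2D",
                       chrom = NA, pos = NA, ref = NA, alt = NA,
                       context3 = NA, is_missense = TRUE,
                       oncokb_class = "vus")
    if (i > 10)  # benign carriers always co-mutated in NFE2L2
      rows <- rbind(rows, data.frame(
        patient_id = paste0("P", i), sample_id = "S", gene = "NFE2L2",
        protein_change = "p.B2C", chrom = NA, pos = NA, ref = NA,
        alt = NA, context3 = NA, is_missense = TRUE,
        oncokb_class = "oncogenic"))
    rows
  }))
  cls <- c("KEAP1:p.A1V" = "pathogenic", "KEAP1:p.C2D" = "benign")
  r <- or_mutex(cls, pts, mut, "KEAP1", c("KEAP1", "NFE2L2", "CUL3"))
  # [[0,10],[10,0]] with 0.5 correction -> OR = (0.5*0.5)/(10.5*10.5)
  expect_equal(r$or_point, 0.25 / 110.25)
  expect_lt(r$or_point, 1)
  # identical co-mutation rates give OR 1
  cls_same <- c("KEAP1:p.A1V" = "pathogenic", "KEAP1:p.C2D" = "pathogenic")
  under <- quiet(or_mutex(cls_same, pts, mut, "KEAP1",
                          c("KEAP1", "NFE2L2")))
  expect_true(under$underpowered)
})

test_that("TMB-adjusted logistic recovers effects and flags separation", {
  set.seed(91)
  n <- 3000
  tmbh <- rbinom(n, 1, 0.4)
  mut <- rbinom(n, 1, plogis(-1 + 0.8 * tmbh))
  y <- rbinom(n, 1, plogis(0.2 - 1.0 * mut + 0.7 * tmbh))
  fit <- tmb_adjusted_logistic(data.frame(pathway_oncogenic = y,
                                          reclassified_mut = mut,
                                          tmb_high = tmbh))
  expect_false(fit$separation)
  expect_lt(abs(fit$coefficients[["mut"]] - (-1.0)), 0.2)
  # null predictors give a near-zero coefficient
  y0 <- rbinom(n, 1, 0.5)
  fit0 <- tmb_adjusted_logistic(data.frame(pathway_oncogenic = y0,
                                           reclassified_mut = mut,
                                           tmb_high = tmbh))
  expect_lt(abs(fit0$coefficients[["mut"]]), 0.15)
  # outcome fully determined by tmb_high: separation flagged
  fit_sep <- tmb_adjusted_logistic(data.frame(pathway_oncogenic = tmbh,
                                              reclassified_mut = mut,
                                              tmb_high = tmbh))
  expect_true(fit_sep$separation)
  expect_error(tmb_adjusted_logistic(data.frame(
    pathway_oncogenic = rep(1, 20), reclassified_mut = rbinom(20, 1, 0.5),
    tmb_high = rbinom(20, 1, 0.5))), "constant")
})
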