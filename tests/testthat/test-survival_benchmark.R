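toy_patients <- function(n, t_end, event, t_entry = 0) {
  data.frame(patient_id = paste0("P", seq_len(n)), panel_id = "panel_A",
             t_dx = 0, t_entry = t_entry, t_end = t_end, event = event)
}

test_that("gene strata follow the precedence and panel rules", {
  pts <- data.frame(patient_id = c("P1", "P2", "P3", "P4"),
                    panel_id = c("A", "A", "A", "B"))
  mut <- data.frame(
    patient_id = c("P1", "P1", "P2", "P4"), sample_id = "S",
    gene = "KEAP1",
    protein_change = c("p.A1V", "p.C2D", "p.E3F", "p.A1V"),
    chrom = NA, pos = NA, ref = NA, alt = NA, context3 = NA,
    is_missense = TRUE,
    oncokb_class = c("oncogenic", "vus", "vus", "vus"))
  cls <- c("KEAP1:p.C2D" = "pathogenic", "KEAP1:p.E3F" = "benign",
           "KEAP1:p.A1V" = "pathogenic")
  cov <- list(A = "KEAP1", B = "TP53")
  got <- assign_gene_strata(pts, mut, cls, "KEAP1", cov)
  # oncogenic outranks a pathogenic VUS carried by the same patient
  expect_equal(unname(got["P1"]), "oncogenic")
  expect_equal(unname(got["P2"]), "reclassified_benign")
  expect_equal(unname(got["P3"]), "no_mutation")
  expect_equal(unname(got["P4"]), "excluded")  # panel lacks the gene
})

test_that("stabilized IPTW matches closed-form weights on the 6-patient fixture", {
  pts <- data.frame(patient_id = paste0("P", 1:6),
                    x = c(0, 0, 0, 1, 1, 1))
  g <- c(1, 0, 0, 1, 1, 0)
  w <- estimate_iptw(pts, g, covariates = "x")
  # e(0) = 1/3, e(1) = 2/3, marginal 1/2
  expect_equal(unname(w$weights), c(1.5, 0.75, 0.75, 0.75, 0.75, 1.5))
  expect_lt(abs(mean(w$weights) - 1), 0.2)
})

test_that("IPTW degenerates to unit weights without confounding and errors on separation", {
  set.seed(5)
  pts <- data.frame(patient_id = paste0("P", 1:400),
                    x = rnorm(400))
  g <- rbinom(400, 1, 0.4)  # independent of x
  w <- estimate_iptw(pts, g, covariates = "x")
  expect_lt(max(abs(w$weights - 1)), 0.35)
  expect_lt(max(abs(w$balance$smd_after)), 0.25)
  sep <- data.frame(patient_id = paste0("P", 1:40), x = rep(0:1, each = 20))
  expect_error(estimate_iptw(sep, sep$x, covariates = "x"), "positivity")
})

test_that("unit-weight untruncated weighted Cox equals the classical fit", {
  set.seed(13)
  n <- 150
  grp <- rbinom(n, 1, 0.5)
  tt <- rexp(n, 0.05 * exp(0.6 * grp))
  dd <- toy_patients(n, pmin(tt, 30), as.integer(tt <= 30))
  dd$group <- grp
  ours <- weighted_cox(dd)
  ref <- survival::coxph(survival::Surv(t_end, event) ~ group, data = dd)
  expect_equal(ours$log_hr, unname(coef(ref)), tolerance = 1e-8)
})

test_that("delayed entry changes risk sets exactly as the hand-coded partial likelihood says", {
  dd <- data.frame(patient_id = paste0("P", 1:6), t_dx = 0,
                   t_entry = c(0, 0, 2, 4, 1, 3),
                   t_end = c(5, 8, 6, 9, 3, 7),
                   event = c(1, 0, 1, 1, 1, 0),
                   group = c(1, 1, 1, 0, 0, 0))
  got <- weighted_cox(dd)
  bhat <- optimize(function(b) -oracle_coxpl(b, dd$t_entry, dd$t_end,
                                             dd$event, dd$group),
                   c(-5, 5))$minimum
  expect_equal(got$log_hr, bhat, tolerance = 1e-4)
  untrunc <- dd
  untrunc$t_entry <- 0
  expect_false(isTRUE(all.equal(weighted_cox(untrunc)$log_hr,
                                got$log_hr, tolerance = 1e-4)))
})

test_that("weighted Cox recovers a true HR of 2 without confounding", {
  set.seed(17)
  est <- replicate(30, {
    n <- 800
    grp <- rbinom(n, 1, 0.4)
    tt <- rexp(n, 0.03 * exp(log(2) * grp))
    dd <- toy_patients(n, pmin(tt, 48), as.integer(tt <= 48))
    dd$group <- grp
    weighted_cox(dd)$log_hr
  })
  expect_lt(abs(mean(est) - log(2)), 0.1)
})

test_that("RR is the ratio of the two hazard ratios", {
  mk <- function(hr) structure(list(hr = hr), class = "cox_result")
  expect_equal(rr_survival(mk(2.0), mk(1.25))$rr, 1.6)
  expect_equal(rr_survival(mk(1.7), mk(1.7))$rr, 1.0)
})

test_that("weighted KM matches the hand product-limit and drops small strata", {
  dd <- toy_patients(3, c(1, 2, 3), c(1, 1, 1))
  dd$stratum <- "all"
  km <- weighted_km(dd, min_stratum = 1)
  expect_equal(km$surv, c(2/3, 1/3, 0))
  # doubling all weights leaves the curve unchanged
  km2 <- weighted_km(dd, weights = rep(2, 3), min_stratum = 1)
  expect_equal(km2$surv, km$surv)
  # a 9-patient stratum is dropped under the default minimum
  dd2 <- toy_patients(19, 1:19, rep(1, 19))
  dd2$stratum <- rep(c("small", "big"), c(9, 10))
  expect_warning(km3 <- weighted_km(dd2), "dropped")
  expect_false(any(km3$stratum == "small"))
  # unit weights reproduce the classical estimator on random data
  set.seed(23)
  tt <- rexp(40, 0.1); ev <- rbinom(40, 1, 0.7)
  dd3 <- toy_patients(40, tt, ev)
  dd3$stratum <- "all"
  km4 <- weighted_km(dd3, min_stratum = 1)
  ref <- survival::survfit(survival::Surv(tt, ev) ~ 1)
  expect_equal(km4$surv[km4$n_event > 0],
               ref$surv[ref$n.event > 0], tolerance = 1e-12)
})

test_that("double-mutant strata exclude oncogenic carriers and recover additive hazards", {
  pts <- data.frame(patient_id = c("P1", "P2", "P3"),
                    panel_id = "panel_A", t_dx = 0, t_entry = 0,
                    t_end = c(10, 12, 14), event = 1)
  mut <- data.frame(
    patient_id = c("P1", "P1", "P2", "P2"), sample_id = "S",
    gene = c("A", "B", "A", "B"),
    protein_change = c("p.A1V", "p.A1V", "p.C2D", "p.A1V"),
    chrom = NA, pos = NA, ref = NA, alt = NA, context3 = NA,
    is_missense = TRUE,
    oncokb_class = c("vus", "vus", "oncogenic", "vus"))
  cls <- c("A:p.A1V" = "pathogenic", "B:p.A1V" = "pathogenic",
           "A:p.C2D" = "pathogenic")
  got <- quiet(double_mutant_analysis(pts, mut, cls, "A", "B",
                                      min_stratum = 1))
  expect_equal(unname(got$strata["P1"]), "double")
  expect_true(is.na(got$strata["P2"]))  # oncogenic in A -> excluded
  expect_equal(unname(got$strata["P3"]), "neither")
})

test_that("discovery/confirmation restricts the confirmation family", {
  disc <- data.frame(id = 1:4, p = c(0.01, 0.02, 0.04, 0.05))
  got <- discovery_confirmation(disc, function(row) row$p * 2, fdr = 0.1)
  expect_true(all(got$discovery$significant))  # BH: all q = 0.05 <= 0.1
  expect_equal(nrow(got$confirmation), 4)
  # no hits: confirmation skipped
  none <- discovery_confirmation(data.frame(p = c(0.8, 0.9)),
                                 function(row) row$p)
  expect_null(none$confirmation)
  # single hit: confirmation q equals its p (family of one)
  one <- discovery_confirmation(data.frame(p = c(0.001, 0.9)),
                                function(row) 0.3, fdr = 0.1)
  expect_equal(one$confirmation$q, 0.3)
})
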