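test_that("the generator is deterministic under a fixed seed", {
  cfg <- sim_config(n_patients = 150, seed = 99)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$patients, b$patients)
  expect_identical(a$mutations, b$mutations)
  expect_identical(a$scores, b$scores)
  c2 <- generate_cohort(sim_config(n_patients = 150, seed = 100))
  expect_false(identical(a$patients$t_end, c2$patients$t_end))
})

test_that("config validation catches inconsistent pathways and profiles", {
  expect_error(sim_config(pathways = list(X = list(genes = "NOPE",
                                                   excl_or = 1))),
               "NOPE")
  bad_prof <- default_context_profile()
  bad_prof$prob <- bad_prof$prob * 2
  expect_error(sim_config(context_profile = bad_prof), "sum to 1")
})

test_that("cohort structure obeys the domain invariants", {
  ch <- generate_cohort(sim_config(n_patients = 300, seed = 5))
  p <- ch$patients
  expect_true(all(p$t_dx <= p$t_entry & p$t_entry < p$t_end))
  expect_true(all(p$tmb >= 0))
  expect_true(all(ch$mutations$oncokb_class %in% c("oncogenic", "vus")))
  expect_true(all(ch$mutations$patient_id %in% p$patient_id))
  # context middle base equals ref
  expect_true(all(substr(ch$mutations$context3, 2, 2) ==
                    ch$mutations$ref))
  # scores exist for every observed unique variant
  keys <- unique(variant_key(ch$mutations$gene,
                             ch$mutations$protein_change))
  expect_setequal(rownames(ch$scores), keys)
  # binding residues are positive integers
  expect_true(all(ch$binding_map$residue >= 1))
})

test_that("null hazard config yields near-zero naive Cox estimates", {
  genes <- default_genes()
  genes$loghr_oncogenic <- genes$loghr_pathvus <- genes$loghr_benignvus <- 0
  est <- vapply(1:3, function(s) {
    cfg <- sim_config(n_patients = 3000, seed = 30 + s, genes = genes,
                      confounding = list(covariate = "smoking",
                                         mut_logodds = 0, loghr = 0))
    ch <- generate_cohort(cfg)
    dd <- ch$patients
    carriers <- unique(ch$mutations$patient_id[ch$mutations$gene ==
                                                 "KEAP1"])
    dd$group <- as.integer(dd$patient_id %in% carriers)
    weighted_cox(dd)$log_hr
  }, numeric(1))
  expect_lt(abs(mean(est)), 0.1)
})

test_that("mutation contexts are drawn i.i.d. from the configured profile", {
  cfg <- sim_config(n_patients = 50, seed = 1)
  ctx <- generate_mutation_contexts(cfg, 2000, seed = 8)
  expect_equal(nrow(ctx), 2000)
  # C>A categories carry weight 6/ (mean over profile); empirical share
  # within 4 sd of expectation
  p_ca <- sum(cfg$context_profile$prob[cfg$context_profile$ref == "C" &
                                         cfg$context_profile$alt == "A"])
  share <- mean(ctx$ref == "C" & ctx$alt == "A")
  expect_lt(abs(share - p_ca), 4 * sqrt(p_ca * (1 - p_ca) / 2000))
})

test_that("configured score separations match the analytic Beta AUROC", {
  cfg <- sim_config(n_patients = 100, seed = 2)
  m <- cfg$methods[cfg$methods$name == "deep_struct", ]
  target <- beta_auroc(m$path_a, m$path_b, m$benign_a, m$benign_b)
  set.seed(77)
  emp <- auroc_delong(rbeta(5000, m$path_a, m$path_b),
                      rbeta(5000, m$benign_a, m$benign_b))$auroc
  expect_lt(abs(emp - target), 0.02)
})

test_that("pathway exclusivity at OR 1 leaves driver co-occurrence independent", {
  ok <- 0
  for (s in 1:40) {
    cfg <- sim_config(
      n_patients = 600, seed = 300 + s,
      pathways = list(NRF2 = list(genes = c("KEAP1", "NFE2L2", "CUL3"),
                                  excl_or = 1)))
    ch <- generate_cohort(cfg)
    drv <- ch$truth$driver[, match(c("KEAP1", "NFE2L2"),
                                   cfg$genes$symbol)]
    tab <- table(factor(drv[, 1], c(FALSE, TRUE)),
                 factor(drv[, 2], c(FALSE, TRUE)))
    p <- suppressWarnings(stats::chisq.test(tab)$p.value)
    ok <- ok + (is.na(p) || p > 0.01)
  }
  expect_gte(ok, 36)  # ~95% of seeds consistent with independence
})

test_that("cohort TSV bundle round-trips through the readers", {
  ch <- generate_cohort(sim_config(n_patients = 120, seed = 55))
  dir <- withr::local_tempdir()
  paths <- write_cohort(ch, dir)
  mut <- quiet(read_mutation_table(paths["mutations"]))
  expect_equal(nrow(mut), nrow(ch$mutations))
  expect_equal(attr(mut, "n_rejected"), 0)
  cl <- quiet(read_clinical_table(paths["clinical"]))
  expect_equal(nrow(cl), 120)
  sc <- quiet(read_score_table(paths["scores"]))
  expect_equal(sort(rownames(sc)), sort(rownames(ch$scores)))
  pw <- read_pathway_table(paths["pathways"])
  expect_equal(sort(names(pw)), sort(names(ch$pathways)))
  bm <- read_binding_map(paths["binding"])
  expect_equal(nrow(bm), nrow(ch$binding_map))
})
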