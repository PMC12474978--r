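# End-to-end orchestration: simulate (optional) -> calibrate -> enabled
# benchmarks -> ensemble; fixed-column TSV outputs plus a JSON manifest so
# reruns with the same config and seed reproduce every file.

#' Run the full benchmark pipeline on a cohort
#'
#' Calibrates every method (learned cutpoints against known-oncogenic vs
#' simulated-neutral scores), classifies VUSs, then runs the enabled
#' benchmarks and writes one TSV per module plus a JSON manifest.
#'
#' @param cohort A `vb_cohort` (from [generate_cohort()]) or a list with
#'   the same elements assembled from files.
#' @param out_dir Output directory; NULL skips file output.
#' @param benchmarks Character subset of c("roc", "binding", "survival",
#'   "mutex", "ensemble").
#' @param survival_gene Gene for the survival benchmark (default KEAP1).
#' @param seed Integer seed for the stochastic stages (negative-class
#'   upsampling, split, forest).
#' @param fdr_levels Named FDR levels per family.
#' @return List of benchmark results (calibration, roc, binding, survival,
#'   mutex, ensemble, manifest).
#' @export
run_pipeline <- function(cohort, out_dir = NULL,
                         benchmarks = c("roc", "binding", "survival",
                                        "mutex", "ensemble"),
                         survival_gene = "KEAP1", seed = 1,
                         fdr_levels = c(roc = 0.05, survival = 0.1,
                                        mutex = 0.1, binding = 0.1)) {
  res <- list()
  mut <- cohort$mutations
  keys_all <- variant_key(mut$gene, mut$protein_change)
  onc_keys <- unique(keys_all[mut$oncokb_class %in%
                                c("oncogenic", "likely_oncogenic")])
  vus_keys <- unique(keys_all[mut$oncokb_class %in% c("vus", "unknown")])
  scores <- cohort$scores
  methods <- cohort$config$methods
  # negative class: simulated neutral scores drawn from each method's
  # benign distribution (stand-in for annotation-rich benign SNPs)
  n_neg <- max(length(onc_keys), 500)
  neg_scores <- with_seed(derive_seed(seed, "neg_class"), {
    m <- matrix(NA_real_, n_neg, nrow(methods),
                dimnames = list(sprintf("NEG:%d", seq_len(n_neg)),
                                methods$name))
    for (j in seq_len(nrow(methods))) {
      s <- rbeta(n_neg, methods$benign_a[j], methods$benign_b[j])
      if (methods$orientation[j] == "lower_pathogenic") s <- 1 - s
      m[, j] <- s
    }
    m
  })
  # calibration per method, then VUS classification
  specs <- cutpoints <- classif <- list()
  for (j in seq_len(nrow(methods))) {
    nm <- methods$name[j]
    specs[[nm]] <- method_spec(nm, orientation = methods$orientation[j],
                               calibration_mode = "learned_cutoff")
    pos <- scores[intersect(onc_keys, rownames(scores)), nm]
    cutpoints[[nm]] <- youden_cutpoint(pos, neg_scores[, nm],
                                       specs[[nm]]$orientation)
    vk <- intersect(vus_keys, rownames(scores))
    classif[[nm]] <- classify_variants(setNames(scores[vk, nm], vk),
                                       specs[[nm]], cutpoints[[nm]])
  }
  res$calibration <- calibration_report(cutpoints, specs)

  if ("roc" %in% benchmarks) {
    pop_keys <- keys_all[mut$oncokb_class %in%
                           c("oncogenic", "likely_oncogenic")]
    pop_keys <- pop_keys[pop_keys %in% rownames(scores)]
    neg_up <- upsample_negatives(seq_len(n_neg), length(pop_keys), seed)
    roc_rows <- lapply(methods$name, function(nm) {
      r <- auroc_delong(orient_scores(scores[pop_keys, nm], specs[[nm]]),
                        orient_scores(neg_scores[neg_up, nm], specs[[nm]]),
                        level = "population")
      data.frame(method = nm, stratum = r$stratum, level = r$level,
                 auroc = r$auroc, ci_low = r$ci_low, ci_high = r$ci_high,
                 n_pos = r$n_pos, n_neg = r$n_neg)
    })
    res$roc <- do.call(rbind, roc_rows)
    pos_m <- vapply(methods$name, function(nm)
      orient_scores(scores[pop_keys, nm], specs[[nm]]), numeric(length(pop_keys)))
    neg_m <- vapply(methods$name, function(nm)
      orient_scores(neg_scores[neg_up, nm], specs[[nm]]),
      numeric(length(neg_up)))
    ok <- stats::complete.cases(pos_m)
    okn <- stats::complete.cases(neg_m)
    res$roc_comparisons <- compare_methods(pos_m[ok, , drop = FALSE],
                                           neg_m[okn, , drop = FALSE])
  }

  if ("binding" %in% benchmarks) {
    umut <- mut[!duplicated(keys_all), , drop = FALSE]
    part <- partition_binding(umut, cohort$binding_map)
    res$binding <- lapply(setNames(methods$name, methods$name),
                          function(nm) or_binding(classif[[nm]], part))
  }

  if ("survival" %in% benchmarks) {
    res$survival <- lapply(setNames(methods$name, methods$name),
                           function(nm)
                             survival_contrasts(cohort, classif[[nm]],
                                                survival_gene))
  }

  if ("mutex" %in% benchmarks) {
    res$mutex <- mutex_battery(cohort$pathways, classif,
                               cohort$patients, mut,
                               coverage = cohort$coverage,
                               fdr = fdr_levels[["mutex"]])
    res$mutex_rates <- do.call(rbind, lapply(names(classif), function(mth)
      do.call(rbind, lapply(names(cohort$pathways), function(pw)
        data.frame(method = mth, pathway = pw,
                   rate = pathway_rate(
                     res$mutex[res$mutex$method == mth, , drop = FALSE],
                     pw, cohort$pathways[[pw]]))))))
  }

  if ("ensemble" %in% benchmarks) {
    res$ensemble <- run_ensemble_benchmark(cohort, onc_keys, neg_scores,
                                           seed = seed)
  }

  res$classifications <- classif
  if (!is.null(out_dir)) res$manifest <- write_bundle(res, out_dir, seed)
  res
}

# Scores oriented so higher = more pathogenic, for rank-based analyses.
orient_scores <- function(s, spec) {
  if (spec$orientation == "lower_pathogenic") -s else s
}

# Both IPTW-weighted contrasts (pathogenic vs none, benign vs none) for
# one gene, plus the RR metric with bootstrap CI.
survival_contrasts <- function(cohort, classifications, gene,
                               bootstrap_b = 100, seed = 1) {
  strata <- assign_gene_strata(cohort$patients, cohort$mutations,
                               classifications, gene, cohort$coverage)
  dd <- cohort$patients
  dd$stratum <- strata[dd$patient_id]
  fit_one <- function(data, grp, truncate = FALSE) {
    sub <- data[data$stratum %in% c(grp, "no_mutation"), , drop = FALSE]
    sub$group <- as.integer(sub$stratum == grp)
    w <- estimate_iptw(sub, sub$group, truncate = truncate)
    list(cox = weighted_cox(sub, w$weights, gene = gene,
                            contrast = paste0(grp, "_vs_none")),
         weights = w)
  }
  path <- fit_one(dd, "reclassified_pathogenic")
  ben <- fit_one(dd, "reclassified_benign")
  rr <- rr_survival(path$cox, ben$cox,
                    fit_fun = function(d) c(
                      fit_one(d, "reclassified_pathogenic", TRUE)$cox$hr,
                      fit_one(d, "reclassified_benign", TRUE)$cox$hr),
                    data = dd, bootstrap_b = bootstrap_b, seed = seed)
  list(strata = strata, cox_pathogenic = path$cox, cox_benign = ben$cox,
       balance = path$weights$balance, rr = rr)
}

run_ensemble_benchmark <- function(cohort, onc_keys, neg_scores, seed) {
  pos <- cohort$scores[intersect(onc_keys, rownames(cohort$scores)), ,
                       drop = FALSE]
  X <- rbind(pos, neg_scores)
  y <- c(rep(1L, nrow(pos)), rep(0L, nrow(neg_scores)))
  genes <- c(sub(":.*$", "", rownames(pos)),
             rep("NEG", nrow(neg_scores)))
  keep <- stats::complete.cases(X)
  X <- X[keep, , drop = FALSE]; y <- y[keep]; genes <- genes[keep]
  sp <- split_train_test(nrow(X), y, seed = seed)
  pre <- zscore_preprocess(X[sp$train, , drop = FALSE],
                           X[sp$test, , drop = FALSE])
  model <- train_ensemble(pre$train, y[sp$train], cv_scheme = "kfold5",
                          seed = seed)
  baseline <- names(which.max(vapply(colnames(X), function(nm)
    auc_rank(X[sp$test, nm][y[sp$test] == 1],
             X[sp$test, nm][y[sp$test] == 0]), numeric(1))))
  ev <- evaluate_and_compare(model, pre$apply, y[sp$test],
                             baseline_scores = X[sp$test, baseline])
  c(ev, list(model = model, baseline = baseline))
}

write_bundle <- function(res, out_dir, seed) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  put <- function(df, name) {
    p <- file.path(out_dir, paste0(name, ".tsv"))
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    files <<- c(files, p)
  }
  if (!is.null(res$calibration)) put(res$calibration, "calibration")
  if (!is.null(res$roc)) put(res$roc, "roc")
  if (!is.null(res$roc_comparisons)) put(res$roc_comparisons,
                                         "roc_comparisons")
  if (!is.null(res$binding)) {
    bd <- do.call(rbind, lapply(names(res$binding), function(nm) {
      x <- res$binding[[nm]]
      data.frame(method = nm, a = x$a, b = x$b, c = x$c, d = x$d,
                 or = x$or_point, ci_low = x$ci_low, ci_high = x$ci_high,
                 p = x$p)
    }))
    bd$q <- bh_adjust(bd$p)
    put(bd, "binding")
  }
  if (!is.null(res$survival)) {
    sv <- do.call(rbind, lapply(names(res$survival), function(nm) {
      x <- res$survival[[nm]]
      data.frame(method = nm,
                 contrast = c(x$cox_pathogenic$contrast,
                              x$cox_benign$contrast),
                 hr = c(x$cox_pathogenic$hr, x$cox_benign$hr),
                 ci_low = c(x$cox_pathogenic$ci_low, x$cox_benign$ci_low),
                 ci_high = c(x$cox_pathogenic$ci_high,
                             x$cox_benign$ci_high),
                 p = c(x$cox_pathogenic$p, x$cox_benign$p),
                 rr = x$rr$rr)
    }))
    sv$q <- bh_adjust(sv$p)
    put(sv, "survival")
  }
  if (!is.null(res$mutex)) put(res$mutex, "mutex")
  if (!is.null(res$mutex_rates)) put(res$mutex_rates, "mutex_rates")
  manifest <- list(
    package_version = as.character(utils::packageVersion("vepbench")),
    seed = seed, files = basename(files),
    n_methods = nrow(res$calibration),
    assumptions = c(
      "variant identity = gene + protein change",
      "stratum precedence oncogenic > reclassified_pathogenic > reclassified_benign",
      "uncertain-class VUS carriers fall in no_mutation",
      "OR_binding computed at mutation level"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  manifest
}
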