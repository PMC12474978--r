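# Benchmark 3: association of reclassified VUSs with overall survival.
# Gene-level strata, stabilized IPTW with balance diagnostics, weighted
# Cox PH from diagnosis left-truncated at cohort entry (sequencing),
# weighted KM, the relative-risk-of-survival (RR) metric, double-mutant
# strata, and two-stage discovery/confirmation FDR logic.

#' Stratify patients by gene-level mutation annotation
#'
#' Groups: "oncogenic" (any known oncogenic/likely-oncogenic mutation in
#' the gene), else "reclassified_pathogenic" (any VUS the method calls
#' pathogenic), else "reclassified_benign", else "no_mutation". Patients
#' whose panel does not cover the gene are "excluded". Carriers of only
#' uncertain/missing-class VUSs fall in no_mutation by default.
#'
#' @param patients Patient data.frame.
#' @param mutations Mutation data.frame.
#' @param classifications Named vector (variant key -> class) for VUSs.
#' @param gene Gene symbol.
#' @param coverage Optional panel coverage list; NULL covers everyone.
#' @param exclude_uncertain If TRUE, carriers of only uncertain-class VUSs
#'   are excluded instead of falling in no_mutation.
#' @return Named character vector patient_id -> group.
#' @export
assign_gene_strata <- function(patients, mutations, classifications, gene,
                               coverage = NULL, exclude_uncertain = FALSE) {
  if (!gene %in% mutations$gene && !is.null(coverage) &&
      !any(vapply(coverage, function(g) gene %in% g, logical(1))))
    stop_vb("unknown gene: %s", gene)
  mg <- mutations[mutations$gene == gene, , drop = FALSE]
  keys <- variant_key(mg$gene, mg$protein_change, mg$chrom, mg$pos,
                      mg$ref, mg$alt)
  onc <- mg$oncokb_class %in% c("oncogenic", "likely_oncogenic")
  is_vus <- mg$oncokb_class %in% c("vus", "unknown")
  cls <- classifications[keys]
  cls[is.na(cls)] <- "missing"
  grp_of <- function(pid) {
    sel <- mg$patient_id == pid
    if (!any(sel)) return("no_mutation")
    if (any(onc[sel])) return("oncogenic")
    vsel <- sel & is_vus
    if (any(cls[vsel] == "pathogenic")) return("reclassified_pathogenic")
    if (any(cls[vsel] == "benign")) return("reclassified_benign")
    if (exclude_uncertain && any(vsel)) return("excluded")
    "no_mutation"
  }
  out <- vapply(patients$patient_id, grp_of, character(1))
  if (!is.null(coverage)) {
    covered <- vapply(patients$panel_id,
                      function(p) gene %in% (coverage[[p]] %||% character(0)),
                      logical(1))
    out[!covered] <- "excluded"
  }
  setNames(out, patients$patient_id)
}

DEFAULT_COVARIATES <- c("stage", "age", "sex", "race", "histology",
                        "smoking", "tmb", "msi_score", "prior_treatment",
                        "metastasis")

smd_one <- function(x, g, w) {
  wm <- function(x, w) sum(w * x) / sum(w)
  wv <- function(x, w) {
    mu <- wm(x, w); sum(w * (x - mu)^2) / sum(w)
  }
  m1 <- wm(x[g == 1], w[g == 1]); m0 <- wm(x[g == 0], w[g == 0])
  s <- sqrt((wv(x[g == 1], w[g == 1]) + wv(x[g == 0], w[g == 0])) / 2)
  if (s == 0) return(0)
  (m1 - m0) / s
}

#' Stabilized inverse-probability-of-treatment weights
#'
#' Propensity for group membership by a main-effects logistic model on
#' baseline covariates. Stabilized weights: P(group)/e(x) for the group
#' arm and (1 - P(group))/(1 - e(x)) for the reference arm. Standardized
#' mean differences per covariate (factors expanded to indicators) are
#' reported before and after weighting.
#'
#' @param patients Patient data.frame (one row per patient in the two
#'   arms).
#' @param group_indicator Binary vector (1 = group of interest).
#' @param covariates Covariate column names (defaults to the clinical
#'   baseline set present in `patients`).
#' @param truncate If TRUE, fitted propensities are truncated at their
#'   1st/99th percentiles before weighting (off by default; useful for
#'   bootstrap refits on small arms).
#' @return A `weight_set`: list(weights (named by patient_id), propensity,
#'   balance data.frame(covariate, smd_before, smd_after)).
#' @export
estimate_iptw <- function(patients, group_indicator,
                          covariates = NULL, truncate = FALSE) {
  covariates <- covariates %||%
    intersect(DEFAULT_COVARIATES,
              names(patients)[colSums(!is.na(patients)) > 0])
  g <- as.integer(group_indicator)
  if (sum(g == 1) < 2 || sum(g == 0) < 2)
    stop_vb("estimate_iptw: need >= 2 patients per arm")
  dd <- patients[, covariates, drop = FALSE]
  dd <- dd[, vapply(dd, function(x)
    length(unique(x[!is.na(x)])) > 1, logical(1)), drop = FALSE]
  if (ncol(dd) == 0) {
    ps <- rep(mean(g), length(g))
  } else {
    fit <- suppressWarnings(
      glm(g ~ ., data = cbind(g = g, dd), family = binomial()))
    ps <- predict(fit, type = "response")
  }
  if (truncate)
    ps <- pmin(pmax(ps, quantile(ps, 0.01)), quantile(ps, 0.99))
  # positivity: error where a weight would explode (treated at ps ~ 0,
  # reference at ps ~ 1) or the model separates the arms completely;
  # ps ~ 0 among reference patients alone leaves weights near 1
  at0 <- ps < 1e-6; at1 <- ps > 1 - 1e-6
  if (any(at0 & g == 1) || any(at1 & g == 0) || (any(at0) && any(at1)))
    stop_vb("estimate_iptw: positivity violation (fitted propensity at 0/1)")
  p_marg <- mean(g)
  w <- ifelse(g == 1, p_marg / ps, (1 - p_marg) / (1 - ps))
  names(w) <- patients$patient_id
  # balance on indicator-expanded covariates
  bal <- do.call(rbind, lapply(names(dd), function(v) {
    x <- dd[[v]]
    if (is.numeric(x)) {
      cols <- list(x); nms <- v
    } else {
      lv <- unique(as.character(x))
      cols <- lapply(lv, function(l) as.numeric(as.character(x) == l))
      nms <- paste(v, lv, sep = "=")
    }
    do.call(rbind, lapply(seq_along(cols), function(i)
      data.frame(covariate = nms[i],
                 smd_before = smd_one(cols[[i]], g, rep(1, length(g))),
                 smd_after = smd_one(cols[[i]], g, w),
                 stringsAsFactors = FALSE)))
  }))
  structure(list(weights = w, propensity = ps, balance = bal),
            class = "weight_set")
}

#' @export
print.weight_set <- function(x, ...) {
  cat(sprintf("<weight_set> n = %d, mean weight %.3f, max |SMD| %.3f -> %.3f\n",
              length(x$weights), mean(x$weights),
              if (nrow(x$balance)) max(abs(x$balance$smd_before)) else NA,
              if (nrow(x$balance)) max(abs(x$balance$smd_after)) else NA))
  invisible(x)
}

#' Weighted left-truncated Cox proportional hazards fit
#'
#' Partial likelihood with per-patient case weights; time origin at
#' diagnosis, risk sets admit a patient only on (t_entry, t_end] (delayed
#' entry at sequencing). Robust sandwich variance is used for the CI since
#' weighting invalidates the naive information-based variance.
#'
#' @param data data.frame with t_entry, t_end, event and a binary `group`
#'   column (1 = contrast arm, 0 = reference).
#' @param weights Case weights (default 1).
#' @param gene,contrast Bookkeeping labels.
#' @return A `cox_result`: gene, contrast, hr, ci_low, ci_high, log_hr,
#'   se, p, n_group, n_ref, n_events, weighted.
#' @export
weighted_cox <- function(data, weights = NULL, gene = "", contrast = "") {
  if (sum(data$event) < 1) stop_vb("weighted_cox: no events")
  if (length(unique(data$group)) < 2)
    stop_vb("weighted_cox: all subjects in one arm")
  w <- weights %||% rep(1, nrow(data))
  data$.id <- seq_len(nrow(data))
  data$.w <- w
  fit <- survival::coxph(
    survival::Surv(t_entry, t_end, event) ~ group,
    data = data, weights = .w, id = .id, robust = TRUE)
  beta <- unname(coef(fit)[1])
  se <- sqrt(diag(fit$var))[1]
  structure(list(gene = gene, contrast = contrast,
                 hr = exp(beta), log_hr = beta, se = se,
                 ci_low = exp(beta - 1.96 * se),
                 ci_high = exp(beta + 1.96 * se),
                 p = 2 * pnorm(-abs(beta / se)),
                 n_group = sum(data$group == 1),
                 n_ref = sum(data$group == 0),
                 n_events = sum(data$event),
                 weighted = !is.null(weights)),
            class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("<cox_result> %s %s: HR %.3f [%.3f, %.3f], p = %.3g (n = %d vs %d, %d events%s)\n",
              x$gene, x$contrast, x$hr, x$ci_low, x$ci_high, x$p,
              x$n_group, x$n_ref, x$n_events,
              if (x$weighted) ", IPTW" else ""))
  invisible(x)
}

#' Relative risk of survival (RR) for one gene
#'
#' RR = HR(reclassified pathogenic vs no mutation) /
#' HR(reclassified benign vs no mutation); higher RR means a method better
#' separates outcome-relevant VUSs. The CI comes from a patient-level
#' nonparametric bootstrap that re-runs both weighted fits on each
#' resample; replicates where an arm empties are dropped and counted, and
#' more than 20% drops is an error.
#'
#' @param cox_pathogenic,cox_benign `cox_result`s sharing the reference
#'   arm.
#' @param fit_fun Optional function(data) -> c(hr_pathogenic, hr_benign)
#'   refitting both weighted models; required for the bootstrap CI.
#' @param data Patient-level data.frame passed to `fit_fun` (resampled by
#'   row).
#' @param bootstrap_b Number of bootstrap replicates.
#' @param seed Integer seed.
#' @return An `rr_result`: rr, ci_low, ci_high, hr_pathogenic, hr_benign,
#'   n_boot_used, n_boot_dropped.
#' @export
rr_survival <- function(cox_pathogenic, cox_benign, fit_fun = NULL,
                        data = NULL, bootstrap_b = 200, seed = 1) {
  rr <- cox_pathogenic$hr / cox_benign$hr
  ci <- c(NA_real_, NA_real_); used <- 0L; dropped <- 0L
  if (!is.null(fit_fun) && !is.null(data)) {
    reps <- with_seed(derive_seed(seed, "rr_boot"), {
      lapply(seq_len(bootstrap_b), function(b) {
        idx <- sample.int(nrow(data), replace = TRUE)
        tryCatch(fit_fun(data[idx, , drop = FALSE]),
                 error = function(e) NULL)
      })
    })
    ok <- !vapply(reps, is.null, logical(1))
    dropped <- sum(!ok)
    if (dropped > 0.2 * bootstrap_b)
      stop_vb("rr_survival: %d of %d bootstrap replicates failed",
              dropped, bootstrap_b)
    ratios <- vapply(reps[ok], function(h) h[1] / h[2], numeric(1))
    used <- sum(ok)
    ci <- unname(quantile(ratios, c(0.025, 0.975)))
  }
  structure(list(rr = rr, ci_low = ci[1], ci_high = ci[2],
                 hr_pathogenic = cox_pathogenic$hr,
                 hr_benign = cox_benign$hr,
                 n_boot_used = used, n_boot_dropped = dropped),
            class = "rr_result")
}

#' @export
print.rr_result <- function(x, ...) {
  cat(sprintf("<rr_result> RR %.3f [%.3f, %.3f] = %.3f / %.3f\n",
              x$rr, x$ci_low, x$ci_high, x$hr_pathogenic, x$hr_benign))
  invisible(x)
}

#' Weighted Kaplan-Meier curves with left truncation
#'
#' Product-limit estimator with IPTW-weighted risk and event counts and
#' delayed entry; strata with fewer than `min_stratum` patients are
#' dropped with a warning.
#'
#' @param data data.frame with t_entry, t_end, event, stratum.
#' @param weights Case weights (default 1).
#' @param min_stratum Minimum patients per stratum (default 10).
#' @return data.frame(stratum, time, surv, n_risk, n_event) of the step
#'   function (weighted counts).
#' @export
weighted_km <- function(data, weights = NULL, min_stratum = 10) {
  w <- weights %||% rep(1, nrow(data))
  sizes <- table(data$stratum)
  keep_lv <- names(sizes)[sizes >= min_stratum]
  if (length(keep_lv) < length(sizes))
    warning(sprintf("dropped %d stratum(a) with < %d patients",
                    length(sizes) - length(keep_lv), min_stratum))
  if (!length(keep_lv)) stop_vb("weighted_km: all strata dropped")
  keep <- data$stratum %in% keep_lv
  dd <- data[keep, , drop = FALSE]
  ww <- w[keep]
  fit <- survival::survfit(
    survival::Surv(t_entry, t_end, event) ~ stratum, data = dd,
    weights = ww)
  strata_n <- fit$strata %||% setNames(length(fit$time), keep_lv[1])
  stratum <- rep(sub("^stratum=", "", names(strata_n)), strata_n)
  data.frame(stratum = stratum, time = fit$time, surv = fit$surv,
             n_risk = fit$n.risk, n_event = fit$n.event,
             stringsAsFactors = FALSE)
}

#' Double-mutant survival analysis for two genes
#'
#' Patients carrying reclassified-pathogenic mutations in both genes form
#' the "double" stratum, in exactly one the "A_only"/"B_only" strata, in
#' neither the "neither" stratum. Carriers of known-oncogenic mutations in
#' either gene are excluded. Returns the four-stratum KM plus pairwise Cox
#' contrasts vs "neither"; a contrast whose stratum is smaller than
#' `min_stratum` is skipped with a log line.
#'
#' @param patients,mutations,classifications As in
#'   [assign_gene_strata()].
#' @param gene_a,gene_b Gene symbols.
#' @param coverage Optional panel coverage.
#' @param covariates If non-NULL, IPTW weights (on these covariates) are
#'   estimated per contrast.
#' @param min_stratum Minimum stratum size (default 10).
#' @return List: strata (named vector), km (data.frame), cox (list of
#'   `cox_result`), skipped (character).
#' @export
double_mutant_analysis <- function(patients, mutations, classifications,
                                   gene_a, gene_b, coverage = NULL,
                                   covariates = NULL, min_stratum = 10) {
  sa <- assign_gene_strata(patients, mutations, classifications, gene_a,
                           coverage)
  sb <- assign_gene_strata(patients, mutations, classifications, gene_b,
                           coverage)
  lab <- rep(NA_character_, nrow(patients))
  pa <- sa[patients$patient_id]; pb <- sb[patients$patient_id]
  excl <- pa %in% c("oncogenic", "excluded") |
    pb %in% c("oncogenic", "excluded")
  ap <- pa == "reclassified_pathogenic"
  bp <- pb == "reclassified_pathogenic"
  lab[!excl & ap & bp] <- "double"
  lab[!excl & ap & !bp] <- "A_only"
  lab[!excl & !ap & bp] <- "B_only"
  lab[!excl & !ap & !bp] <- "neither"
  keep <- !is.na(lab)
  dd <- patients[keep, , drop = FALSE]
  dd$stratum <- lab[keep]
  km <- weighted_km(dd, min_stratum = min_stratum)
  cox <- list(); skipped <- character(0)
  for (st in c("double", "A_only", "B_only")) {
    n_st <- sum(dd$stratum == st)
    if (n_st < min_stratum || sum(dd$stratum == "neither") < min_stratum) {
      skipped <- c(skipped, st)
      vb_log("double_mutant_analysis: contrast %s skipped (n = %d)", st,
             n_st)
      next
    }
    sub <- dd[dd$stratum %in% c(st, "neither"), , drop = FALSE]
    sub$group <- as.integer(sub$stratum == st)
    wts <- NULL
    if (!is.null(covariates))
      wts <- estimate_iptw(sub, sub$group, covariates)$weights
    cox[[st]] <- weighted_cox(sub, wts,
                              gene = paste(gene_a, gene_b, sep = "/"),
                              contrast = paste0(st, "_vs_neither"))
  }
  list(strata = setNames(lab, patients$patient_id), km = km, cox = cox,
       skipped = skipped)
}

#' Two-stage discovery/confirmation FDR logic
#'
#' BH at `fdr` over all discovery comparisons; only discovery-significant
#' hypotheses are re-tested in the confirmation cohort, and confirmation
#' q-values are computed over that reduced family only.
#'
#' @param discovery data.frame with a `p` column (one row per hypothesis).
#' @param confirmation_fit Function(row) -> confirmation p-value, called
#'   for each discovery-significant row.
#' @param fdr FDR level (default 0.1).
#' @return List: discovery (with q, significant), confirmation (with q,
#'   significant; NULL when no discovery hit).
#' @export
discovery_confirmation <- function(discovery, confirmation_fit,
                                   fdr = 0.1) {
  discovery$q <- bh_adjust(discovery$p)
  discovery$significant <- discovery$q <= fdr
  hits <- which(discovery$significant)
  if (!length(hits)) {
    vb_log("discovery_confirmation: no discovery-significant hypothesis")
    return(list(discovery = discovery, confirmation = NULL))
  }
  conf <- discovery[hits, , drop = FALSE]
  conf$p <- vapply(hits, function(i)
    confirmation_fit(discovery[i, , drop = FALSE]), numeric(1))
  conf$q <- bh_adjust(conf$p)
  conf$significant <- conf$q <= fdr
  list(discovery = discovery, confirmation = conf)
}
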