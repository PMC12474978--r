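# Benchmark 4: do reclassified-pathogenic VUSs avoid tumors that already
# carry a known oncogenic driver in the same signaling pathway?
# One-vs-all Fisher battery per (gene, pathway, method), pathway-level
# significant-test rate, OR_mutex, and TMB-adjusted logistic regression.

# Patient-level carrier indicators for one gene.
carrier_flags <- function(patients, mutations, classifications, gene) {
  mg <- mutations[mutations$gene == gene, , drop = FALSE]
  keys <- variant_key(mg$gene, mg$protein_change, mg$chrom, mg$pos,
                      mg$ref, mg$alt)
  cls <- classifications[keys]
  cls[is.na(cls)] <- "missing"
  onc <- mg$oncokb_class %in% c("oncogenic", "likely_oncogenic")
  vus <- mg$oncokb_class %in% c("vus", "unknown")
  list(
    oncogenic = patients$patient_id %in% mg$patient_id[onc],
    path = patients$patient_id %in% mg$patient_id[vus & cls == "pathogenic"],
    benign = patients$patient_id %in% mg$patient_id[vus & cls == "benign"])
}

#' Build the one-vs-all mutual exclusivity 2x2 table
#'
#' Rows: patient carries >= 1 reclassified-pathogenic mutation in the
#' focal gene vs not ("VUSs/no mutation"). Columns: patient carries >= 1
#' known-oncogenic mutation in ANY pathway gene (the focal gene included)
#' vs not. Counts are over the supplied analysis cohort.
#'
#' @param gene Focal gene (must belong to the pathway).
#' @param pathway_genes Character vector of the pathway's genes.
#' @param classifications Named vector (variant key -> class).
#' @param patients,mutations Cohort tables.
#' @return 2x2 integer matrix (rows: pathogenic yes/no, cols: pathway
#'   oncogenic yes/no).
#' @export
build_mutex_table <- function(gene, pathway_genes, classifications,
                              patients, mutations) {
  if (!gene %in% pathway_genes)
    stop_vb("gene %s not in the pathway", gene)
  focal <- carrier_flags(patients, mutations, classifications, gene)
  pw_onc <- Reduce(`|`, lapply(pathway_genes, function(g)
    carrier_flags(patients, mutations, classifications, g)$oncogenic))
  matrix(c(sum(focal$path & pw_onc), sum(focal$path & !pw_onc),
           sum(!focal$path & pw_onc), sum(!focal$path & !pw_onc)),
         nrow = 2, byrow = TRUE,
         dimnames = list(c("reclassified_pathogenic", "vus_or_none"),
                         c("pathway_oncogenic", "none")))
}

#' Mutual exclusivity Fisher test for one gene-pathway pair
#'
#' Two-sided exact p by hypergeometric enumeration; log odds ratio with
#' Haldane-Anscombe 0.5 correction at zero cells (the exact p is never
#' corrected). A test is significant for mutual exclusivity when
#' logOR < 0 and q <= 0.1; `q` must be filled in across the whole battery
#' (see [mutex_battery()]) before the flag is final. A zero margin skips
#' the test with a notice.
#'
#' @param table 2x2 counts from [build_mutex_table()].
#' @param gene,pathway,method Bookkeeping labels.
#' @param fdr Significance level on q (default 0.1).
#' @return A `mutex_result` (single-test q = p) or NULL when skipped.
#' @export
mutex_fisher <- function(table, gene = "", pathway = "", method = "",
                         fdr = 0.1) {
  x <- as.integer(t(table))
  if (sum(x[1:2]) == 0 || sum(x[3:4]) == 0 ||
      sum(x[c(1, 3)]) == 0 || sum(x[c(2, 4)]) == 0) {
    vb_log("mutex_fisher: zero margin for %s/%s, test skipped", gene,
           pathway)
    return(NULL)
  }
  f <- fisher_exact_2x2(table)
  structure(list(gene = gene, pathway = pathway, method = method,
                 a = f$a, b = f$b, c = f$c, d = f$d,
                 log_or = f$log_or, p = f$p, q = f$p,
                 significant = f$log_or < 0 && f$p <= fdr),
            class = "mutex_result")
}

#' Run the full one-vs-all mutual exclusivity battery
#'
#' One Fisher test per (gene, pathway, method); BH correction across every
#' test performed in the invocation (the single FDR family). Significance:
#' logOR < 0 and q <= `fdr`.
#'
#' @param pathways Named list pathway -> gene vector.
#' @param classifications_by_method Named list method -> named class
#'   vector.
#' @param patients,mutations Cohort tables.
#' @param coverage Optional panel coverage (per-gene panel filtering).
#' @param fdr FDR level (default 0.1).
#' @return data.frame(method, pathway, gene, a, b, c, d, log_or, p, q,
#'   significant).
#' @export
mutex_battery <- function(pathways, classifications_by_method, patients,
                          mutations, coverage = NULL, fdr = 0.1) {
  rows <- list()
  for (mth in names(classifications_by_method)) {
    cls <- classifications_by_method[[mth]]
    for (pw in names(pathways)) {
      for (g in pathways[[pw]]) {
        pts <- if (is.null(coverage)) patients else
          filter_panel(patients, coverage, g)
        if (!nrow(pts)) next
        tab <- build_mutex_table(g, pathways[[pw]], cls, pts, mutations)
        res <- mutex_fisher(tab, gene = g, pathway = pw, method = mth,
                            fdr = fdr)
        if (is.null(res)) next
        rows[[length(rows) + 1]] <- data.frame(
          method = mth, pathway = pw, gene = g, a = res$a, b = res$b,
          c = res$c, d = res$d, log_or = res$log_or, p = res$p,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(NULL)
  out$q <- bh_adjust(out$p)
  out$significant <- out$log_or < 0 & out$q <= fdr
  out
}

#' Pathway-level mutual exclusivity rate
#'
#' Number of significant mutually exclusive tests divided by the number of
#' genes in the pathway; the denominator counts ALL pathway genes,
#' including untestable ones.
#'
#' @param results data.frame with `pathway` and `significant` columns (one
#'   row per testable gene).
#' @param pathway Pathway name.
#' @param pathway_genes The pathway's full gene list.
#' @return Rate in [0, 1].
#' @export
pathway_rate <- function(results, pathway, pathway_genes) {
  sub <- results[results$pathway == pathway, , drop = FALSE]
  sum(sub$significant) / length(pathway_genes)
}

#' OR_mutex: pathogenic vs benign carriers avoiding pathway drivers
#'
#' Over carriers of reclassified mutations in the focal gene: rows split
#' reclassified-pathogenic vs reclassified-benign carriers; columns split
#' by carrying a known-oncogenic mutation in ANOTHER pathway gene (the
#' focal gene is excluded from the column). OR < 1 means pathogenic
#' carriers avoid co-occurring drivers more than benign carriers do.
#'
#' @param classifications Named class vector.
#' @param patients,mutations Cohort tables.
#' @param gene Focal gene.
#' @param pathway_genes The pathway's genes.
#' @return An `enrichment_result`, or a list with `underpowered = TRUE`
#'   when a carrier class is empty.
#' @export
or_mutex <- function(classifications, patients, mutations, gene,
                     pathway_genes) {
  focal <- carrier_flags(patients, mutations, classifications, gene)
  others <- setdiff(pathway_genes, gene)
  other_onc <- if (length(others))
    Reduce(`|`, lapply(others, function(g)
      carrier_flags(patients, mutations, classifications, g)$oncogenic))
  else rep(FALSE, nrow(patients))
  path_c <- focal$path & !focal$benign
  ben_c <- focal$benign & !focal$path
  if (!any(path_c) || !any(ben_c)) {
    vb_log("or_mutex: %s underpowered (a carrier class is empty)", gene)
    return(list(underpowered = TRUE, gene = gene))
  }
  a <- sum(path_c & other_onc); b <- sum(path_c & !other_onc)
  cc <- sum(ben_c & other_onc); d <- sum(ben_c & !other_onc)
  binding_fisher(c(a, b, cc, d), group = paste0("OR_mutex:", gene))
}

#' TMB-adjusted mutual exclusivity logistic regression
#'
#' Fits pathway_oncogenic ~ reclassified_mut + tmb_high by maximum
#' likelihood. A negative reclassified-mutation coefficient indicates
#' mutual exclusivity independent of TMB-high status. Complete separation
#' is detected and flagged rather than returning a silently diverged fit.
#'
#' @param samples data.frame with logical/0-1 columns pathway_oncogenic,
#'   reclassified_mut, tmb_high.
#' @return A `logistic_result`: coefficients, se, p (named vectors) and
#'   `separation` flag.
#' @export
tmb_adjusted_logistic <- function(samples) {
  if (nrow(samples) < 10) stop_vb("need >= 10 samples")
  y <- as.integer(samples$pathway_oncogenic)
  if (length(unique(y)) < 2) stop_vb("outcome is constant")
  dd <- data.frame(y = y,
                   mut = as.integer(samples$reclassified_mut),
                   tmb_high = as.integer(samples$tmb_high))
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    glm(y ~ mut + tmb_high, data = dd, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  sm <- summary(fit)$coefficients
  separation <- sep_warn || any(abs(coef(fit)) > 15) ||
    any(sm[, "Std. Error"] > 100)
  structure(list(coefficients = coef(fit), se = sm[, "Std. Error"],
                 p = sm[, "Pr(>|z|)"], separation = separation,
                 n = nrow(samples)),
            class = "logistic_result")
}

#' @export
print.logistic_result <- function(x, ...) {
  cat(sprintf("<logistic_result> n = %d%s\n", x$n,
              if (x$separation) " [separation detected]" else ""))
  print(round(cbind(coef = x$coefficients, se = x$se, p = x$p), 4))
  invisible(x)
}
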