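# Benchmark 1: rediscovery of known driver mutations. AUROC by the
# Mann-Whitney estimator with DeLong structural-component variance; paired
# DeLong tests between methods with BH correction; per-gene sensitivity.

#' Build the ROC instance multiset at mutation or population level
#'
#' Mutation level counts each unique variant once; population level keeps
#' one instance per occurrence, reflecting real-world mutation frequency.
#'
#' @param mutations Mutation data.frame.
#' @param level "mutation" or "population".
#' @return Character vector of variant keys (with repeats at population
#'   level).
#' @export
build_instances <- function(mutations, level = c("mutation", "population")) {
  level <- match.arg(level)
  keys <- variant_key(mutations$gene, mutations$protein_change,
                      mutations$chrom, mutations$pos, mutations$ref,
                      mutations$alt)
  if (level == "mutation") unique(keys) else keys
}

#' Upsample the negative class to match the positive class size
#'
#' Negatives are sampled with replacement to size n_target so ROC analysis
#' runs on balanced classes.
#'
#' @param negatives Character vector of negative-class keys.
#' @param n_target Target size.
#' @param seed Integer seed.
#' @return Character vector of length n_target.
#' @export
upsample_negatives <- function(negatives, n_target, seed = 1) {
  if (!length(negatives)) stop_vb("cannot upsample an empty negative class")
  if (n_target < 1) stop_vb("n_target must be >= 1")
  with_seed(derive_seed(seed, "upsample"),
            sample(negatives, n_target, replace = TRUE))
}

# DeLong structural components: list(auc, v10, v01, var).
delong_components <- function(pos, neg) {
  m <- length(pos); n <- length(neg)
  r_all <- rank(c(pos, neg), ties.method = "average")
  r_pos <- rank(pos, ties.method = "average")
  r_neg <- rank(neg, ties.method = "average")
  # midrank identities (Sun & Xu): V10_i = (R_i - r_i)/n, V01_j = 1-(R_j-r_j)/m
  v10 <- (r_all[seq_len(m)] - r_pos) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - r_neg) / m
  auc <- (sum(r_all[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
  v <- if (m > 1 && n > 1) var(v10) / m + var(v01) / n else 0
  list(auc = auc, v10 = v10, v01 = v01, var = v)
}

#' AUROC with DeLong 95% confidence interval
#'
#' Rank/pair-counting AUROC (ties count 1/2) with the DeLong
#' structural-component variance and a normal-approximation CI clipped to
#' [0, 1]. Zero variance (perfect or degenerate separation) collapses the
#' CI to a point and sets `degenerate = TRUE`.
#'
#' @param pos_scores,neg_scores Score vectors for the two classes.
#' @param level,stratum Bookkeeping labels carried into the result.
#' @param conf Confidence level (default 0.95).
#' @return A `roc_result` list: auroc, ci_low, ci_high, n_pos, n_neg,
#'   var_auroc, degenerate, level, stratum.
#' @export
auroc_delong <- function(pos_scores, neg_scores, level = "mutation",
                         stratum = "all", conf = 0.95) {
  pos <- pos_scores[!is.na(pos_scores)]
  neg <- neg_scores[!is.na(neg_scores)]
  if (!length(pos) || !length(neg))
    stop_vb("auroc_delong: both classes must be non-empty")
  d <- delong_components(pos, neg)
  z <- qnorm(1 - (1 - conf) / 2)
  half <- z * sqrt(d$var)
  structure(list(auroc = d$auc,
                 ci_low = max(0, d$auc - half),
                 ci_high = min(1, d$auc + half),
                 n_pos = length(pos), n_neg = length(neg),
                 var_auroc = d$var, degenerate = d$var == 0,
                 level = level, stratum = stratum),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUROC %.4f [%.4f, %.4f] (n+ = %d, n- = %d, %s/%s)%s\n",
              x$auroc, x$ci_low, x$ci_high, x$n_pos, x$n_neg, x$level,
              x$stratum, if (x$degenerate) " [degenerate variance]" else ""))
  invisible(x)
}

#' Paired DeLong test for two correlated AUROCs
#'
#' Both methods must score the same positive and negative instances.
#' Degenerate variance with a zero AUROC difference (e.g. identical
#' scores) reports p = 1; degenerate with a nonzero difference is flagged
#' with p = NA rather than fabricating significance.
#'
#' @param pos_a,neg_a Scores of method A on positives/negatives.
#' @param pos_b,neg_b Scores of method B on the same instances, same order.
#' @return List: delta_auc, ci, p, degenerate.
#' @export
delong_test <- function(pos_a, neg_a, pos_b, neg_b) {
  if (length(pos_a) != length(pos_b) || length(neg_a) != length(neg_b))
    stop_vb("delong_test: instance sets differ between methods")
  da <- delong_components(pos_a, neg_a)
  db <- delong_components(pos_b, neg_b)
  m <- length(pos_a); n <- length(neg_a)
  vd <- if (m > 1 && n > 1)
    var(da$v10 - db$v10) / m + var(da$v01 - db$v01) / n else 0
  delta <- da$auc - db$auc
  if (vd <= 0) {
    p <- if (abs(delta) < 1e-12) 1 else NA_real_
    return(list(delta_auc = delta, ci = c(delta, delta), p = p,
                degenerate = TRUE))
  }
  se <- sqrt(vd)
  z <- delta / se
  list(delta_auc = delta,
       ci = c(delta - 1.96 * se, delta + 1.96 * se),
       p = 2 * pnorm(-abs(z)), degenerate = FALSE)
}

#' Planned AUROC comparisons between methods with FDR correction
#'
#' Comparison plan: within each methodological class, the top-performing
#' method versus the others; then each class's top performer versus the
#' overall best method. With no class assignment all methods form one
#' class. BH q-values are computed across all comparisons performed.
#'
#' @param pos_scores,neg_scores Matrices (instance x method) of scores on
#'   shared positive/negative instances.
#' @param classes Optional named character vector method -> class label.
#' @return data.frame(method_a, method_b, auc_a, auc_b, delta_auc, ci_low,
#'   ci_high, p, q, comparison).
#' @export
compare_methods <- function(pos_scores, neg_scores, classes = NULL) {
  methods <- colnames(pos_scores)
  if (length(methods) < 2) stop_vb("need >= 2 methods to compare")
  if (!identical(colnames(neg_scores), methods))
    stop_vb("instance sets differ: method columns do not match")
  if (is.null(classes))
    classes <- setNames(rep("all", length(methods)), methods)
  aucs <- vapply(methods, function(mm)
    delong_components(pos_scores[, mm], neg_scores[, mm])$auc, numeric(1))
  rows <- list()
  add_cmp <- function(a, b, tag) {
    dt <- delong_test(pos_scores[, a], neg_scores[, a],
                      pos_scores[, b], neg_scores[, b])
    rows[[length(rows) + 1]] <<- data.frame(
      method_a = a, method_b = b, auc_a = aucs[[a]], auc_b = aucs[[b]],
      delta_auc = dt$delta_auc, ci_low = dt$ci[1], ci_high = dt$ci[2],
      p = dt$p, comparison = tag, stringsAsFactors = FALSE)
  }
  class_best <- character(0)
  for (cl in unique(classes)) {
    members <- methods[classes[methods] == cl]
    best <- members[which.max(aucs[members])]
    class_best[cl] <- best
    for (other in setdiff(members, best))
      add_cmp(best, other, paste0("within_class:", cl))
  }
  overall <- methods[which.max(aucs)]
  for (best in setdiff(class_best, overall))
    add_cmp(overall, best, "class_best_vs_overall")
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out
}

#' Per-gene true positive rate of a classifier
#'
#' TPR per gene among truth-positive variants with a non-missing
#' classification; genes with no classifiable truth positives are omitted
#' with a warning.
#'
#' @param classifications Named character vector (variant key -> class).
#' @param truth_pos Character vector of truth-positive variant keys.
#' @param genes Named character vector (variant key -> gene).
#' @return data.frame(gene, tpr, n) where n counts truth positives for the
#'   gene (classified or not).
#' @export
per_gene_tpr <- function(classifications, truth_pos, genes) {
  truth_pos <- intersect(truth_pos, names(genes))
  by_gene <- split(truth_pos, genes[truth_pos])
  rows <- lapply(names(by_gene), function(g) {
    keys <- by_gene[[g]]
    cls <- classifications[keys]
    usable <- !is.na(cls) & cls != "missing"
    if (!any(usable)) {
      warning(sprintf("gene %s omitted: no non-missing classification", g))
      return(NULL)
    }
    data.frame(gene = g, tpr = mean(cls[usable] == "pathogenic"),
               n = length(keys), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene = character(), tpr = numeric(), n = integer())
  out
}

#' ROC curve points (FPR, TPR) for export
#'
#' @param pos_scores,neg_scores Score vectors (higher = more pathogenic).
#' @return data.frame(threshold, fpr, tpr), thresholds descending.
#' @export
roc_points <- function(pos_scores, neg_scores) {
  thr <- sort(unique(c(pos_scores, neg_scores, Inf)), decreasing = TRUE)
  data.frame(threshold = thr,
             fpr = vapply(thr, function(t) mean(neg_scores >= t),
                          numeric(1)),
             tpr = vapply(thr, function(t) mean(pos_scores >= t),
                          numeric(1)))
}
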