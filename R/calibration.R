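# Score calibration: turning raw VEP scores into pathogenic/benign calls.
# Each method declares one of four calibration modes; cutpoints are
# re-learned per dataset (data-specific thresholds).

#' Youden-type optimal cutpoint
#'
#' Scans every unique observed score as a candidate threshold and maximizes
#' sensitivity + specificity. The classification rule is boundary-inclusive
#' on the pathogenic side: for "higher_pathogenic" a score >= t is called
#' pathogenic, for "lower_pathogenic" a score <= t. When several thresholds
#' attain the maximum, the final threshold is their median.
#'
#' @param pos_scores Scores of known-pathogenic variants.
#' @param neg_scores Scores of benign variants.
#' @param orientation "higher_pathogenic" or "lower_pathogenic".
#' @return A `cutpoint_result` list: threshold, candidate_maxima, objective,
#'   orientation.
#' @export
youden_cutpoint <- function(pos_scores, neg_scores,
                            orientation = c("higher_pathogenic",
                                            "lower_pathogenic")) {
  orientation <- match.arg(orientation)
  pos_scores <- pos_scores[!is.na(pos_scores)]
  neg_scores <- neg_scores[!is.na(neg_scores)]
  if (!length(pos_scores) || !length(neg_scores))
    stop_vb("youden_cutpoint: both classes must be non-empty")
  if (!all(is.finite(c(pos_scores, neg_scores))))
    stop_vb("youden_cutpoint: scores must be finite")
  cand <- sort(unique(c(pos_scores, neg_scores)))
  obj <- vapply(cand, function(t) {
    if (orientation == "higher_pathogenic")
      mean(pos_scores >= t) + mean(neg_scores < t)
    else
      mean(pos_scores <= t) + mean(neg_scores > t)
  }, numeric(1))
  best <- max(obj)
  maxima <- cand[abs(obj - best) < 1e-12]
  structure(list(threshold = median(maxima), candidate_maxima = maxima,
                 objective = best, orientation = orientation),
            class = "cutpoint_result")
}

#' @export
print.cutpoint_result <- function(x, ...) {
  cat(sprintf("<cutpoint> threshold=%.6g (objective %.4f, %d maximizer(s), %s)\n",
              x$threshold, x$objective, length(x$candidate_maxima),
              x$orientation))
  invisible(x)
}

# Rank-based AUROC with ties counted 1/2 (Mann-Whitney). Internal; the
# DeLong machinery lives in the driver-rediscovery module.
auc_rank <- function(pos, neg) {
  r <- rank(c(pos, neg), ties.method = "average")
  n1 <- length(pos); n2 <- length(neg)
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Select the built-in classification stringency maximizing AUROC
#'
#' Some predictors ship classifications at several uncertainty levels (each
#' excluding a different fraction of low-confidence variants). This picks
#' the level whose retained scores best separate the positive and negative
#' classes; ties go to the level excluding fewest variants.
#'
#' @param classed_scores Named list: label -> list(pos, neg) score vectors.
#' @return The selected label.
#' @export
select_best_class <- function(classed_scores) {
  valid <- Filter(function(x) length(x$pos) > 0 && length(x$neg) > 0,
                  classed_scores)
  if (!length(valid)) stop_vb("select_best_class: no class with both sets")
  aucs <- vapply(valid, function(x) auc_rank(x$pos, x$neg), numeric(1))
  sizes <- vapply(valid, function(x) length(x$pos) + length(x$neg),
                  numeric(1))
  best <- max(aucs)
  tied <- abs(aucs - best) < 1e-12
  names(valid)[tied][which.max(sizes[tied])]
}

#' Benjamini-Hochberg q-values
#'
#' Step-up adjusted p-values (capped at 1, original order restored).
#'
#' @param pvalues Numeric vector of p-values in [0, 1].
#' @return Vector of q-values.
#' @export
bh_adjust <- function(pvalues) {
  if (!length(pvalues)) return(numeric(0))
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop_vb("p-values must lie in [0, 1]")
  p.adjust(pvalues, method = "BH")
}

#' Classify variants by BH q-value threshold
#'
#' Used for predictors that emit a significance p-value against a
#' background model: variants with q <= alpha are pathogenic, all others
#' benign.
#'
#' @param pvalues Named numeric vector (variant key -> p).
#' @param alpha FDR level (default 0.05; the boundary q = alpha is
#'   pathogenic).
#' @return Named character vector of "pathogenic"/"benign".
#' @export
qvalue_classify <- function(pvalues, alpha = 0.05) {
  q <- bh_adjust(pvalues)
  setNames(ifelse(q <= alpha, "pathogenic", "benign"), names(pvalues))
}

#' Classify variants under a method's calibration mode
#'
#' learned_cutoff applies the boundary-inclusive threshold rule in the
#' method's orientation; builtin_classes maps provider labels through the
#' spec's class_map (which may yield "uncertain"); missing scores are
#' always "missing", never "benign".
#'
#' @param scores Named vector: numeric scores (learned_cutoff /
#'   fixed threshold) or character provider labels (builtin_classes).
#' @param spec A [method_spec()].
#' @param cutpoint A [youden_cutpoint()] result (required for
#'   learned_cutoff when `spec$threshold` is NULL).
#' @return Named character vector with values in
#'   pathogenic/benign/uncertain/missing.
#' @export
classify_variants <- function(scores, spec, cutpoint = NULL) {
  out <- rep("missing", length(scores))
  names(out) <- names(scores)
  present <- !is.na(scores)
  if (spec$calibration_mode == "builtin_classes") {
    mapped <- unname(spec$class_map[as.character(scores[present])])
    mapped[is.na(mapped)] <- "uncertain"
    out[present] <- mapped
    return(out)
  }
  thr <- spec$threshold
  if (is.null(thr)) {
    if (is.null(cutpoint))
      stop_vb("learned_cutoff classification requires a cutpoint")
    thr <- cutpoint$threshold
  }
  s <- as.numeric(scores[present])
  patho <- if (spec$orientation == "higher_pathogenic") s >= thr else
    s <= thr
  out[present] <- ifelse(patho, "pathogenic", "benign")
  out
}

#' Calibration report for a set of methods
#'
#' @param cutpoints Named list of `cutpoint_result`s.
#' @param specs Named list of [method_spec()]s.
#' @return data.frame(method, mode, orientation, threshold, objective,
#'   n_candidates).
#' @export
calibration_report <- function(cutpoints, specs) {
  do.call(rbind, lapply(names(specs), function(nm) {
    cp <- cutpoints[[nm]]
    data.frame(method = nm, mode = specs[[nm]]$calibration_mode,
               orientation = specs[[nm]]$orientation,
               threshold = if (!is.null(cp)) cp$threshold else
                 specs[[nm]]$threshold %||% NA_real_,
               objective = if (!is.null(cp)) cp$objective else NA_real_,
               n_candidates = if (!is.null(cp))
                 length(cp$candidate_maxima) else NA_integer_,
               stringsAsFactors = FALSE)
  }))
}
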