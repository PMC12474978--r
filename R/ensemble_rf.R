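# Random-forest ensemble over per-method VEP scores: z-score
# preprocessing fitted on training rows only, class-stratified 75:25
# split, 5-fold or gene-holdout CV for mtry tuning, test metrics and
# feature importances.

#' Z-score standardization fitted on training data
#'
#' Centering and scale (sample standard deviation, n - 1 divisor) are
#' estimated on the training rows only and applied to both tables;
#' constant features are dropped with a warning.
#'
#' @param train_scores Numeric matrix (instances x features).
#' @param apply_scores Optional second matrix standardized with the
#'   training parameters.
#' @return List: train, apply (or NULL), center, scale, dropped.
#' @export
zscore_preprocess <- function(train_scores, apply_scores = NULL) {
  if (nrow(train_scores) < 2) stop_vb("need >= 2 training rows")
  ctr <- colMeans(train_scores)
  scl <- apply(train_scores, 2, sd)
  dropped <- colnames(train_scores)[is.na(scl) | scl == 0]
  if (length(dropped) == ncol(train_scores))
    stop_vb("all features constant")
  if (length(dropped))
    warning(sprintf("dropped constant feature(s): %s",
                    paste(dropped, collapse = ", ")))
  keep <- setdiff(colnames(train_scores), dropped)
  std <- function(m)
    sweep(sweep(m[, keep, drop = FALSE], 2, ctr[keep]), 2, scl[keep], "/")
  list(train = std(train_scores),
       apply = if (!is.null(apply_scores)) std(apply_scores) else NULL,
       center = ctr[keep], scale = scl[keep], dropped = dropped)
}

#' Class-stratified train/test split
#'
#' @param n Number of instances, or a vector of instance ids.
#' @param labels Binary/character class labels (length n).
#' @param ratio Training fraction (default 0.75).
#' @param seed Integer seed.
#' @return List of index vectors: train, test (disjoint, covering 1..n).
#' @export
split_train_test <- function(n, labels, ratio = 0.75, seed = 1) {
  if (length(n) == 1) n <- seq_len(n)
  labels <- as.character(labels)
  if (any(table(labels) < 2)) stop_vb("each class needs >= 2 instances")
  train <- with_seed(derive_seed(seed, "split"), {
    unlist(lapply(unique(labels), function(l) {
      idx <- which(labels == l)
      sample(idx, round(ratio * length(idx)))
    }), use.names = FALSE)
  })
  list(train = sort(train), test = sort(setdiff(seq_along(labels), train)))
}

make_folds <- function(n, k, seed) {
  with_seed(derive_seed(seed, "folds"),
            split(sample.int(n), rep_len(seq_len(k), n)))
}

make_gene_folds <- function(genes, k, seed) {
  ug <- unique(genes)
  if (length(ug) < k)
    stop_vb("fewer genes (%d) than folds (%d)", length(ug), k)
  gf <- with_seed(derive_seed(seed, "gene_folds"),
                  split(sample(ug), rep_len(seq_len(k), length(ug))))
  lapply(gf, function(gs) which(genes %in% gs))
}

#' Train the random-forest score ensemble
#'
#' Tunes mtry by cross-validated AUROC under either randomly sampled
#' 5-fold CV or gene-holdout CV (folds partition genes, so no gene spans
#' train and validation), then refits on all training data at the tuned
#' mtry.
#'
#' @param train Standardized feature matrix.
#' @param labels Binary labels (1 = pathogenic).
#' @param cv_scheme "kfold5" or "gene_holdout".
#' @param genes Gene per instance (required for gene_holdout).
#' @param mtry_grid Candidate mtry values (default 1, 2, 3, floor sqrt p).
#' @param n_trees Trees per forest (default 500).
#' @param seed Integer seed.
#' @return An `ensemble_model`: model (randomForest), mtry, cv_auroc
#'   (named by mtry), cv_scheme, importance.
#' @export
train_ensemble <- function(train, labels,
                           cv_scheme = c("kfold5", "gene_holdout"),
                           genes = NULL, mtry_grid = NULL, n_trees = 500,
                           seed = 1) {
  cv_scheme <- match.arg(cv_scheme)
  if (length(unique(labels)) < 2) stop_vb("labels are constant")
  if (ncol(train) < 2) stop_vb("need >= 2 features")
  y <- factor(labels, levels = c(0, 1))
  mtry_grid <- mtry_grid %||%
    sort(unique(pmin(ncol(train), c(1, 2, 3, floor(sqrt(ncol(train)))))))
  folds <- if (cv_scheme == "kfold5") make_folds(nrow(train), 5, seed)
  else make_gene_folds(genes, 5, seed)
  cv_auc <- vapply(mtry_grid, function(mt) {
    aucs <- vapply(folds, function(val_idx) {
      tr <- setdiff(seq_len(nrow(train)), val_idx)
      if (length(unique(y[tr])) < 2 || length(unique(y[val_idx])) < 2)
        return(NA_real_)
      fit <- with_seed(derive_seed(seed, paste0("rf", mt)),
                       randomForest::randomForest(
                         train[tr, , drop = FALSE], y[tr], mtry = mt,
                         ntree = n_trees))
      pr <- predict(fit, train[val_idx, , drop = FALSE], type = "prob")[, "1"]
      auc_rank(pr[y[val_idx] == 1], pr[y[val_idx] == 0])
    }, numeric(1))
    mean(aucs, na.rm = TRUE)
  }, numeric(1))
  best_mtry <- mtry_grid[which.max(cv_auc)]
  final <- with_seed(derive_seed(seed, "rf_final"),
                     randomForest::randomForest(train, y, mtry = best_mtry,
                                                ntree = n_trees,
                                                importance = TRUE))
  imp <- randomForest::importance(final, type = 2)[, 1]
  structure(list(model = final, mtry = best_mtry,
                 cv_auroc = setNames(cv_auc, mtry_grid),
                 cv_scheme = cv_scheme,
                 importance = imp),
            class = "ensemble_model")
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat(sprintf("<ensemble_model> %s, tuned mtry = %d, CV AUROC %.4f\n",
              x$cv_scheme, x$mtry, max(x$cv_auroc)))
  invisible(x)
}

#' Evaluate the ensemble on held-out data and compare with a baseline VEP
#'
#' Accuracy/sensitivity/specificity at the 0.5 predicted-probability
#' threshold plus AUROC; paired DeLong comparison of ensemble predictions
#' vs baseline scores on identical test instances. Test instances missing
#' a baseline score are dropped from the comparison only (logged).
#'
#' @param model An `ensemble_model`.
#' @param test Standardized test feature matrix.
#' @param labels Binary test labels.
#' @param baseline_scores Optional baseline method scores aligned with
#'   test rows.
#' @return List: auroc (a `roc_result`), accuracy, sensitivity,
#'   specificity, comparison (delong_test result or NULL), importance.
#' @export
evaluate_and_compare <- function(model, test, labels,
                                 baseline_scores = NULL) {
  pr <- predict(model$model, test, type = "prob")[, "1"]
  y <- as.integer(labels)
  pred <- as.integer(pr >= 0.5)
  res <- list(
    auroc = auroc_delong(pr[y == 1], pr[y == 0]),
    accuracy = mean(pred == y),
    sensitivity = if (any(y == 1)) mean(pred[y == 1] == 1) else NA_real_,
    specificity = if (any(y == 0)) mean(pred[y == 0] == 0) else NA_real_,
    comparison = NULL, importance = model$importance)
  if (!is.null(baseline_scores)) {
    ok <- !is.na(baseline_scores)
    if (!all(ok))
      vb_log("evaluate_and_compare: %d instance(s) lack baseline scores",
             sum(!ok))
    res$comparison <- delong_test(pr[ok & y == 1], pr[ok & y == 0],
                                  baseline_scores[ok & y == 1],
                                  baseline_scores[ok & y == 0])
  }
  res
}
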