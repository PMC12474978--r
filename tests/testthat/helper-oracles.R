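# Independent reference implementations used as oracles; deliberately
# naive (enumeration / brute force), never sharing code with the package.

# BH step-up, written from the definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in m:1) {
    val <- min(prev, p[o[i]] * m / i)
    q[o[i]] <- val
    prev <- val
  }
  q
}

# AUROC by explicit all-pairs counting, ties 1/2.
oracle_auc <- function(pos, neg) {
  s <- 0
  for (x in pos) for (y in neg)
    s <- s + if (x > y) 1 else if (x == y) 0.5 else 0
  s / (length(pos) * length(neg))
}

# Two-sided Fisher exact p by full enumeration with binomial
# coefficients (no dhyper).
oracle_fisher_p <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; n1 <- a + c
  tab_prob <- function(k)
    choose(m1, k) * choose(m2, n1 - k) / choose(m1 + m2, n1)
  ks <- max(0, n1 - m2):min(m1, n1)
  probs <- vapply(ks, tab_prob, numeric(1))
  p_obs <- tab_prob(a)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Exhaustive sensitivity+specificity scan over unique observed scores.
oracle_cutpoint <- function(pos, neg, higher = TRUE) {
  cand <- sort(unique(c(pos, neg)))
  obj <- sapply(cand, function(t) {
    if (higher) mean(pos >= t) + mean(neg < t)
    else mean(pos <= t) + mean(neg > t)
  })
  best <- max(obj)
  maxima <- cand[abs(obj - best) < 1e-12]
  list(threshold = median(maxima), maxima = maxima, objective = best)
}

# Delayed-entry Cox partial log-likelihood for a single binary covariate,
# written from the risk-set definition (Breslow ties).
oracle_coxpl <- function(beta, entry, stop, event, group, w = NULL) {
  if (is.null(w)) w <- rep(1, length(stop))
  ll <- 0
  for (i in which(event == 1)) {
    at_risk <- entry < stop[i] & stop[i] <= stop
    ll <- ll + w[i] * (beta * group[i] -
                         log(sum(w[at_risk] * exp(beta * group[at_risk]))))
  }
  ll
}

# Small deterministic clinical fixture used across reader tests.
write_fixture_clinical <- function(path, n = 4) {
  df <- data.frame(patient_id = paste0("P", seq_len(n)),
                   cohort_id = "C", panel_id = "panel_A",
                   age = 60 + seq_len(n), sex = "F", race = "white",
                   histology = "adeno", stage = "IV", smoking = "ever",
                   prior_treatment = FALSE, metastasis = FALSE,
                   tmb = 5, msi_score = 1,
                   t_dx = 0, t_entry = 3, t_end = 20, event = 1)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  df
}

quiet <- function(expr) {
  old <- options(vepbench.verbose = FALSE)
  on.exit(options(old))
  suppressWarnings(expr)
}
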