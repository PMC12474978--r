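# Benchmark 2: are reclassified-pathogenic VUSs enriched at protein
# binding residues (ligand-binding residues union PPI hotspots)?
# Exact 2x2 machinery is shared with the mutual-exclusivity benchmark:
# two-sided hypergeometric p by enumeration, sample odds ratio with
# Haldane-Anscombe 0.5 correction at zero cells, Woolf log-normal CI.

#' Two-sided Fisher exact test for a 2x2 table
#'
#' The two-sided p-value sums all hypergeometric outcomes (for the fixed
#' margins) whose probability does not exceed that of the observed table.
#' The odds ratio is the sample OR (ad)/(bc), with 0.5 added to every cell
#' when any cell is zero; its 95% CI is the Woolf log-normal interval. The
#' exact p is never continuity-corrected.
#'
#' @param table 2x2 integer matrix, or c(a, b, c, d) row-wise.
#' @return List: a, b, c, d, or_point, log_or, ci_low, ci_high, p,
#'   corrected (TRUE when the 0.5 correction was applied).
#' @export
fisher_exact_2x2 <- function(table) {
  x <- as.integer(if (is.matrix(table)) t(table) else table)
  if (length(x) != 4 || any(x < 0) || any(is.na(x)))
    stop_vb("need four nonnegative counts")
  a <- x[1]; b <- x[2]; cc <- x[3]; d <- x[4]
  m1 <- a + b; m2 <- cc + d; n1 <- a + cc; n2 <- b + d
  if (m1 == 0 || m2 == 0 || n1 == 0 || n2 == 0)
    stop_vb("fisher_exact_2x2: zero margin, test undefined")
  lo <- max(0L, n1 - m2); hi <- min(m1, n1)
  support <- lo:hi
  probs <- dhyper(support, m1, m2, n1)
  p_obs <- dhyper(a, m1, m2, n1)
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  corrected <- any(x == 0)
  xx <- if (corrected) x + 0.5 else x
  or_point <- (xx[1] * xx[4]) / (xx[2] * xx[3])
  se <- sqrt(sum(1 / xx))
  list(a = a, b = b, c = cc, d = d,
       or_point = or_point, log_or = log(or_point),
       ci_low = exp(log(or_point) - 1.96 * se),
       ci_high = exp(log(or_point) + 1.96 * se),
       p = p, corrected = corrected)
}

#' @importFrom stats dhyper
NULL

#' Assign mutations to binding vs non-binding residues
#'
#' A missense mutation is "binding" when its residue index (parsed from
#' the HGVS p. short string) appears in the gene's binding-residue set
#' (ligand union PPI hotspot). Genes absent from the map, and mutations
#' whose protein change cannot be parsed, are "unmapped".
#'
#' @param mutations Mutation data.frame.
#' @param binding_map data.frame(gene, residue, source) from
#'   [read_binding_map()].
#' @return Named character vector (variant key ->
#'   binding/non_binding/unmapped); attribute `n_unparsed`.
#' @export
partition_binding <- function(mutations, binding_map) {
  keys <- variant_key(mutations$gene, mutations$protein_change)
  res_idx <- parse_residue(mutations$protein_change)
  by_gene <- split(binding_map$residue, binding_map$gene)
  out <- vapply(seq_len(nrow(mutations)), function(i) {
    g <- mutations$gene[i]
    if (!g %in% names(by_gene)) return("unmapped")
    if (is.na(res_idx[i])) return("unmapped")
    if (res_idx[i] %in% by_gene[[g]]) "binding" else "non_binding"
  }, character(1))
  n_unparsed <- sum(is.na(res_idx))
  if (n_unparsed > 0)
    vb_log("partition_binding: %d unparseable protein change(s)", n_unparsed)
  out <- setNames(out, keys)
  attr(out, "n_unparsed") <- n_unparsed
  out
}

# "p.V600E" -> 600; NA when the p.<AA><pos><AA> pattern does not match.
parse_residue <- function(protein_change) {
  m <- regmatches(protein_change,
                  regexpr("^p\\.[A-Za-z*]{1,3}([0-9]+)", protein_change))
  out <- rep(NA_real_, length(protein_change))
  hit <- lengths(regmatches(protein_change,
                            gregexpr("^p\\.[A-Za-z*]{1,3}[0-9]+",
                                     protein_change))) > 0
  out[hit] <- as.numeric(sub("^p\\.[A-Za-z*]{1,3}([0-9]+).*$", "\\1",
                             protein_change[hit]))
  out
}

#' Fisher enrichment test on a binding 2x2 table
#'
#' @param table 2x2 counts (rows: binding/non-binding, cols: class).
#' @param group Label carried into the result.
#' @return An `enrichment_result`.
#' @export
binding_fisher <- function(table, group = "") {
  res <- fisher_exact_2x2(table)
  structure(c(list(group = group), res), class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("<enrichment> %s OR %.3f [%.3f, %.3f], p = %.3g (a=%d b=%d c=%d d=%d)\n",
              x$group, x$or_point, x$ci_low, x$ci_high, x$p,
              x$a, x$b, x$c, x$d))
  invisible(x)
}

#' Binding-site odds ratio for reclassified VUSs (OR_binding)
#'
#' Pooled across all genes with binding information: how much more likely
#' are reclassified-pathogenic VUSs to fall on binding residues than
#' reclassified-benign VUSs? Unmapped variants and classes other than
#' pathogenic/benign are excluded. Computed at mutation level (each unique
#' variant once).
#'
#' @param classifications Named vector (variant key -> class), restricted
#'   by the caller to VUSs.
#' @param binding Named vector from [partition_binding()].
#' @return An `enrichment_result` with counts a = pathogenic & binding,
#'   b = pathogenic & non-binding, c = benign & binding, d = benign &
#'   non-binding.
#' @export
or_binding <- function(classifications, binding) {
  keys <- intersect(names(classifications), names(binding))
  cls <- classifications[keys]
  bnd <- binding[keys]
  keep <- cls %in% c("pathogenic", "benign") &
    bnd %in% c("binding", "non_binding")
  cls <- cls[keep]; bnd <- bnd[keep]
  a <- sum(cls == "pathogenic" & bnd == "binding")
  b <- sum(cls == "pathogenic" & bnd == "non_binding")
  cc <- sum(cls == "benign" & bnd == "binding")
  d <- sum(cls == "benign" & bnd == "non_binding")
  if (a + b == 0 || cc + d == 0)
    stop_vb("or_binding: a reclassified class is empty after exclusions")
  binding_fisher(c(a, b, cc, d), group = "OR_binding")
}
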