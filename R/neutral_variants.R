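# SBS96 trinucleotide-context machinery: categories keyed by the
# pyrimidine-strand context (COSMIC convention), used both to estimate a
# tumor-type mutational profile and to simulate matched neutral variants.

BASES <- c("A", "C", "G", "T")
COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

revcomp3 <- function(ctx) {
  vapply(strsplit(ctx, ""), function(b)
    paste(rev(unname(COMPLEMENT[b])), collapse = ""), character(1))
}

#' The 96 pyrimidine-centered substitution categories
#'
#' @return data.frame(context3, ref, alt, label) in canonical COSMIC order
#'   (C>A, C>G, C>T, T>A, T>C, T>G; flanks varying A,C,G,T).
#' @export
sbs96_categories <- function() {
  subs <- rbind(
    expand.grid(ref = "C", alt = c("A", "G", "T"),
                stringsAsFactors = FALSE),
    expand.grid(ref = "T", alt = c("A", "C", "G"),
                stringsAsFactors = FALSE))
  out <- do.call(rbind, lapply(seq_len(nrow(subs)), function(i) {
    g <- expand.grid(p5 = BASES, p3 = BASES, stringsAsFactors = FALSE)
    data.frame(context3 = paste0(g$p5, subs$ref[i], g$p3),
               ref = subs$ref[i], alt = subs$alt[i],
               stringsAsFactors = FALSE)
  }))
  # canonical order: substitution type outer, 5' then 3' flank inner
  out <- out[order(match(out$ref, c("C", "T")), out$alt,
                   substr(out$context3, 1, 1),
                   substr(out$context3, 3, 3)), ]
  out$label <- sprintf("%s[%s>%s]%s", substr(out$context3, 1, 1),
                       out$ref, out$alt, substr(out$context3, 3, 3))
  rownames(out) <- NULL
  out
}

# Map arbitrary-strand (context3, ref, alt) to the pyrimidine-centered
# category label; NA when unmappable.
sbs96_label <- function(context3, ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt); context3 <- toupper(context3)
  ok <- is_single_base(ref) & is_single_base(alt) & ref != alt &
    !is.na(context3) & nchar(context3) == 3 &
    substr(context3, 2, 2) == ref
  out <- rep(NA_character_, length(ref))
  if (!any(ok)) return(out)
  ctx <- context3[ok]; r <- ref[ok]; a <- alt[ok]
  pur <- r %in% c("A", "G")
  ctx[pur] <- revcomp3(ctx[pur])
  a[pur] <- unname(COMPLEMENT[a[pur]])
  r[pur] <- unname(COMPLEMENT[r[pur]])
  out[ok] <- sprintf("%s[%s>%s]%s", substr(ctx, 1, 1), r, a,
                     substr(ctx, 3, 3))
  out
}

#' Estimate a trinucleotide-change profile from observed mutations
#'
#' Computes the empirical distribution of single-base substitutions over
#' the 96 pyrimidine-centered trinucleotide categories, reverse-
#' complementing purine-reference changes. This is the tumor-type
#' mutational profile used to simulate matched neutral variants.
#'
#' @param mutations Mutation data.frame with context3, ref, alt.
#' @param tumor_type Label recorded on the profile.
#' @return A `context_profile`: data.frame of the 96 categories with a
#'   `prob` column; attributes `tumor_type`, `n_source_mutations`,
#'   `n_rejected`.
#' @export
estimate_context_profile <- function(mutations, tumor_type = "pan") {
  lab <- sbs96_label(mutations$context3, mutations$ref, mutations$alt)
  n_rej <- sum(is.na(lab) & (!is.na(mutations$ref) | !is.na(mutations$alt)))
  lab <- lab[!is.na(lab)]
  if (length(lab) == 0) stop_vb("no eligible SNV mutations for profile")
  if (n_rej > 0)
    vb_log("estimate_context_profile: rejected %d ineligible record(s)",
           n_rej)
  cats <- sbs96_categories()
  counts <- table(factor(lab, levels = cats$label))
  cats$prob <- as.numeric(counts) / length(lab)
  structure(cats, class = c("context_profile", "data.frame"),
            tumor_type = tumor_type, n_source_mutations = length(lab),
            n_rejected = n_rej)
}

#' @export
print.context_profile <- function(x, ...) {
  cat(sprintf("<context_profile> tumor_type=%s, %d source mutations, %d/96 categories occupied\n",
              attr(x, "tumor_type"), attr(x, "n_source_mutations"),
              sum(x$prob > 0)))
  invisible(x)
}

validate_profile <- function(profile) {
  if (abs(sum(profile$prob) - 1) > 1e-9)
    stop_vb("context profile does not sum to 1 (sum = %.12f)",
            sum(profile$prob))
  if (any(profile$prob < 0)) stop_vb("negative probability in profile")
  invisible(profile)
}

#' Simulate tumor-type-matched neutral variants
#'
#' Draws variants whose trinucleotide-change categories follow the supplied
#' profile. When per-category site opportunities are given, sampling weight
#' is proportional to profile mass times opportunity count (uniform
#' opportunities reproduce raw profile sampling).
#'
#' @param profile A `context_profile`.
#' @param n Number of variants to draw.
#' @param opportunities Optional named vector of available site counts per
#'   category label; default uniform.
#' @param seed Integer seed; draws are reproducible.
#' @return data.frame(label, context3, ref, alt) of n simulated variants.
#' @export
simulate_neutral_variants <- function(profile, n, opportunities = NULL,
                                      seed = 1) {
  validate_profile(profile)
  if (n == 0) return(profile[0, c("label", "context3", "ref", "alt")])
  w <- profile$prob
  if (!is.null(opportunities)) {
    opp <- opportunities[profile$label]
    opp[is.na(opp)] <- 0
    zero <- w > 0 & opp == 0
    if (any(zero))
      stop_vb("zero opportunities for nonzero-mass category: %s",
              paste(profile$label[zero], collapse = ", "))
    w <- w * opp
    w <- w / sum(w)
  }
  idx <- with_seed(derive_seed(seed, "neutral_sim"),
                   sample.int(96L, n, replace = TRUE, prob = w))
  out <- profile[idx, c("label", "context3", "ref", "alt")]
  rownames(out) <- NULL
  out
}

#' Select annotation-rich negative-control variants
#'
#' Ranks candidate variants by the number of non-missing method scores and
#' returns the top k; ties at the boundary break lexicographically by
#' variant key so selection is deterministic.
#'
#' @param candidates Character vector of variant keys.
#' @param scores Score matrix (rows = variant keys, cols = methods).
#' @param k Number of variants to select.
#' @return Character vector of k selected keys.
#' @export
select_annotation_rich_negatives <- function(candidates, scores, k) {
  if (k > length(candidates))
    stop_vb("k (%d) exceeds number of candidates (%d)", k,
            length(candidates))
  n_ann <- vapply(candidates, function(key) {
    if (!key %in% rownames(scores)) return(0L)
    sum(!is.na(scores[key, ]))
  }, integer(1))
  ord <- order(-n_ann, candidates)
  candidates[ord][seq_len(k)]
}

#' Write / read a 96-row profile TSV
#' @param profile A `context_profile`.
#' @param path TSV path (columns label, context3, ref, alt, prob).
#' @return `path` (write) or a `context_profile` (read).
#' @export
write_context_profile <- function(profile, path) {
  write.table(as.data.frame(profile), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_context_profile
#' @export
read_context_profile <- function(path) {
  raw <- read.delim(path, stringsAsFactors = FALSE)
  cats <- sbs96_categories()
  raw <- raw[match(cats$label, raw$label), ]
  cats$prob <- raw$prob
  validate_profile(structure(cats,
                             class = c("context_profile", "data.frame"),
                             tumor_type = "file",
                             n_source_mutations = NA_integer_))
}
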