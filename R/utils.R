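#' @keywords internal
"_PACKAGE"

#' @importFrom stats aggregate binomial coef glm integrate median pnorm
#'   p.adjust predict qnorm quantile rbeta rbinom rexp rlnorm rnorm runif sd
#'   setNames var vcov rmultinom
#' @importFrom utils read.delim write.table head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic per-component sub-seed: one user seed fans out into
# independent streams so adding one component never perturbs another.
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483647)
}

with_seed <- function(seed, expr) {
  force(seed)  # any RNG use in the seed expression must precede the save
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

vb_log <- function(fmt, ..., verbose = getOption("vepbench.verbose", TRUE)) {
  if (isTRUE(verbose)) message(sprintf(fmt, ...))
  invisible(NULL)
}

stop_vb <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_single_base <- function(x) !is.na(x) & x %in% c("A", "C", "G", "T")
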