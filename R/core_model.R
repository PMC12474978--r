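# Domain containers are plain data.frames with fixed column sets; readers
# enforce invariants record-wise and report (never silently drop) rejects.

MUTATION_COLS <- c("patient_id", "sample_id", "gene", "protein_change",
                   "chrom", "pos", "ref", "alt", "context3",
                   "is_missense", "oncokb_class")

ONCOKB_CLASSES <- c("oncogenic", "likely_oncogenic", "neutral",
                    "likely_neutral", "vus", "unknown")

#' Variant identity key
#'
#' Variants are identified at the protein level by gene plus HGVS p. short
#' change; the genomic coordinate is used only when the protein change is
#' absent.
#'
#' @param gene Gene symbol vector.
#' @param protein_change HGVS p. short strings (e.g. "p.V600E").
#' @param chrom,pos,ref,alt Optional genomic fallback fields.
#' @return Character vector of keys.
#' @export
variant_key <- function(gene, protein_change, chrom = NA, pos = NA,
                        ref = NA, alt = NA) {
  genomic <- paste(chrom, pos, ref, alt, sep = ":")
  ifelse(!is.na(protein_change) & nzchar(protein_change),
         paste(gene, protein_change, sep = ":"),
         paste(gene, genomic, sep = ":"))
}

#' Read a MAF-style mutation table
#'
#' Expects a tab-separated file with MAF column names (Hugo_Symbol,
#' HGVSp_Short, Variant_Classification, Tumor_Sample_Barcode; genomic
#' columns optional). Rows with malformed bases or a context whose middle
#' base disagrees with the reference allele are rejected individually and
#' counted, never silently dropped.
#'
#' @param path Path to a TSV (gzip accepted).
#' @param patient_col Column holding the patient identifier; defaults to
#'   Tumor_Sample_Barcode truncated at the sample suffix if a
#'   `Patient_ID` column is absent.
#' @return A data.frame of mutation records with attribute `n_rejected`.
#' @export
read_mutation_table <- function(path, patient_col = "Patient_ID") {
  if (!file.exists(path)) stop_vb("mutation table not found: %s", path)
  raw <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                    na.strings = c("NA", ""))
  required <- c("Hugo_Symbol", "HGVSp_Short", "Variant_Classification",
                "Tumor_Sample_Barcode")
  miss <- setdiff(required, names(raw))
  if (length(miss))
    stop_vb("mutation table missing required column(s): %s",
            paste(miss, collapse = ", "))
  get_col <- function(nm) if (nm %in% names(raw)) raw[[nm]] else
    rep(NA, nrow(raw))
  pid <- if (patient_col %in% names(raw)) raw[[patient_col]] else
    sub("-T[0-9]+$", "", raw[["Tumor_Sample_Barcode"]])
  okb <- tolower(as.character(get_col("Oncokb_Class")))
  okb[is.na(okb) | !okb %in% ONCOKB_CLASSES] <- "unknown"
  out <- data.frame(
    patient_id = as.character(pid),
    sample_id = as.character(raw[["Tumor_Sample_Barcode"]]),
    gene = as.character(raw[["Hugo_Symbol"]]),
    protein_change = as.character(get_col("HGVSp_Short")),
    chrom = as.character(get_col("Chromosome")),
    pos = suppressWarnings(as.numeric(get_col("Start_Position"))),
    ref = toupper(as.character(get_col("Reference_Allele"))),
    alt = toupper(as.character(get_col("Tumor_Seq_Allele2"))),
    context3 = toupper(as.character(get_col("Ref_Tri"))),
    is_missense = raw[["Variant_Classification"]] == "Missense_Mutation",
    oncokb_class = okb,
    stringsAsFactors = FALSE
  )
  ok <- rep(TRUE, nrow(out))
  has_alleles <- !is.na(out$ref) | !is.na(out$alt)
  bad_base <- has_alleles &
    (!is_single_base(out$ref) | !is_single_base(out$alt) |
       out$ref == out$alt)
  has_ctx <- !is.na(out$context3)
  bad_ctx <- has_ctx & (nchar(out$context3) != 3 |
                          substr(out$context3, 2, 2) != out$ref)
  bad_id <- is.na(out$patient_id) | !nzchar(out$patient_id) |
    is.na(out$gene) | !nzchar(out$gene)
  ok <- !(bad_base | (bad_ctx %in% TRUE) | bad_id)
  n_rej <- sum(!ok)
  if (n_rej > 0)
    vb_log("read_mutation_table: rejected %d malformed record(s)", n_rej)
  res <- out[ok, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_rejected") <- n_rej
  res
}

#' Write a mutation table in the MAF-style dialect the reader accepts
#'
#' @param mutations Mutation data.frame as from [read_mutation_table()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_mutation_table <- function(mutations, path) {
  out <- data.frame(
    Hugo_Symbol = mutations$gene,
    HGVSp_Short = mutations$protein_change,
    Variant_Classification = ifelse(mutations$is_missense,
                                    "Missense_Mutation", "Other"),
    Tumor_Sample_Barcode = mutations$sample_id,
    Patient_ID = mutations$patient_id,
    Chromosome = mutations$chrom,
    Start_Position = mutations$pos,
    Reference_Allele = mutations$ref,
    Tumor_Seq_Allele2 = mutations$alt,
    Ref_Tri = mutations$context3,
    Oncokb_Class = mutations$oncokb_class,
    stringsAsFactors = FALSE
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' Read a clinical/survival table
#'
#' Times are months from diagnosis; ISO-8601 dates are accepted for the
#' diagnosis/sequencing/last-contact columns and converted. Records
#' violating the time ordering dx <= entry <= end are rejected and counted.
#'
#' @param path TSV with columns patient_id, cohort_id, panel_id, covariates
#'   (age, sex, race, histology, stage, smoking, prior_treatment,
#'   metastasis), tmb, msi_score, t_dx, t_entry, t_end, event. Date columns
#'   date_dx/date_entry/date_end may replace the t_* columns.
#' @return data.frame of patient records with attribute `n_rejected`.
#' @export
read_clinical_table <- function(path) {
  if (!file.exists(path)) stop_vb("clinical table not found: %s", path)
  raw <- read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  if (nrow(raw) == 0) {
    warning("clinical table is empty")
    return(empty_patients())
  }
  if (!"patient_id" %in% names(raw))
    stop_vb("clinical table missing required column(s): patient_id")
  if ("tmb" %in% names(raw)) {
    tmb_num <- suppressWarnings(as.numeric(raw$tmb))
    if (any(!is.na(raw$tmb) & is.na(tmb_num)))
      stop_vb("non-numeric tmb value(s) in clinical table")
    raw$tmb <- tmb_num
  }
  if (all(c("date_dx", "date_entry", "date_end") %in% names(raw))) {
    d0 <- as.Date(raw$date_dx)
    raw$t_dx <- 0
    raw$t_entry <- as.numeric(as.Date(raw$date_entry) - d0) / 30.4375
    raw$t_end <- as.numeric(as.Date(raw$date_end) - d0) / 30.4375
  }
  need <- c("t_dx", "t_entry", "t_end", "event")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop_vb("clinical table missing required column(s): %s",
            paste(miss, collapse = ", "))
  cov_cols <- c("cohort_id", "panel_id", "age", "sex", "race", "histology",
                "stage", "smoking", "prior_treatment", "metastasis",
                "tmb", "msi_score")
  for (cc in setdiff(cov_cols, names(raw))) raw[[cc]] <- NA
  ok <- !is.na(raw$t_dx) & !is.na(raw$t_entry) & !is.na(raw$t_end) &
    raw$t_dx <= raw$t_entry & raw$t_entry <= raw$t_end
  n_rej <- sum(!ok)
  if (n_rej > 0)
    vb_log("read_clinical_table: rejected %d record(s) violating time order",
           n_rej)
  res <- raw[ok, c("patient_id", cov_cols, need), drop = FALSE]
  res$event <- as.integer(res$event)
  rownames(res) <- NULL
  attr(res, "n_rejected") <- n_rej
  res
}

empty_patients <- function() {
  data.frame(patient_id = character(), cohort_id = character(),
             panel_id = character(), age = numeric(), sex = character(),
             race = character(), histology = character(), stage = character(),
             smoking = character(), prior_treatment = logical(),
             metastasis = logical(), tmb = numeric(), msi_score = numeric(),
             t_dx = numeric(), t_entry = numeric(), t_end = numeric(),
             event = integer(), stringsAsFactors = FALSE)
}

#' TMB-high and MSI-high flags
#'
#' TMB-high is defined as TMB >= 10 mutations/Mb (boundary inclusive);
#' MSI-high as an MSIsensor score strictly greater than 10. A missing input
#' yields NA, never FALSE.
#'
#' @param tmb Mutations per megabase.
#' @param msi_score MSIsensor score.
#' @return List with logical elements `tmb_high` and `msi_high`.
#' @export
derive_clinical_flags <- function(tmb, msi_score) {
  list(tmb_high = ifelse(is.na(tmb), NA, tmb >= 10),
       msi_high = ifelse(is.na(msi_score), NA, msi_score > 10))
}

#' Read a per-variant score table
#'
#' Wide dbNSFP-style TSV: key columns gene + protein_change, one numeric
#' column per method; "." or empty cells are missing. Duplicate keys with
#' identical scores collapse silently; conflicting duplicates are an error.
#'
#' @param path TSV path.
#' @param methods Character vector of method column names to keep (default:
#'   all non-key columns).
#' @return Numeric matrix, rownames = variant keys, colnames = methods.
#' @export
read_score_table <- function(path, methods = NULL) {
  raw <- read.delim(path, stringsAsFactors = FALSE,
                    na.strings = c("NA", "", "."))
  if (!all(c("gene", "protein_change") %in% names(raw)))
    stop_vb("score table missing key columns gene/protein_change")
  keys <- variant_key(raw$gene, raw$protein_change)
  mcols <- methods %||% setdiff(names(raw), c("gene", "protein_change"))
  m <- as.matrix(raw[, mcols, drop = FALSE])
  storage.mode(m) <- "numeric"
  rownames(m) <- keys
  if (anyDuplicated(keys)) {
    split_idx <- split(seq_along(keys), keys)
    conflict <- vapply(split_idx, function(ix) {
      if (length(ix) == 1) return(FALSE)
      any(apply(m[ix, , drop = FALSE], 2, function(col)
        length(unique(col[!is.na(col)])) > 1))
    }, logical(1))
    if (any(conflict))
      stop_vb("conflicting duplicate scores for key(s): %s",
              paste(names(split_idx)[conflict], collapse = ", "))
    m <- m[!duplicated(keys), , drop = FALSE]
  }
  for (mc in colnames(m)) {
    vb_log("score table: method %s has %d non-missing score(s)",
           mc, sum(!is.na(m[, mc])), verbose = FALSE)
  }
  m
}

#' Read a panel coverage table
#'
#' @param path Two-column TSV (panel_id, gene).
#' @return Named list mapping panel_id to a character vector of genes.
#' @export
read_panel_table <- function(path) {
  raw <- read.delim(path, stringsAsFactors = FALSE)
  cov <- split(raw$gene, raw$panel_id)
  if (any(lengths(cov) == 0)) stop_vb("panel with empty gene set")
  cov
}

#' Read a pathway gene-list table
#'
#' @param path Two-column TSV (pathway, gene).
#' @return Named list mapping pathway name to gene symbols.
#' @export
read_pathway_table <- function(path) {
  raw <- read.delim(path, stringsAsFactors = FALSE)
  pw <- split(raw$gene, raw$pathway)
  if (any(vapply(pw, anyDuplicated, integer(1)) > 0))
    stop_vb("duplicate gene within a pathway")
  pw
}

#' Read a binding-residue map
#'
#' @param path Three-column TSV (gene, residue, source) where source is
#'   "ligand" or "ppi_hotspot".
#' @return data.frame(gene, residue, source).
#' @export
read_binding_map <- function(path) {
  raw <- read.delim(path, stringsAsFactors = FALSE)
  if (any(raw$residue < 1)) stop_vb("binding residue index < 1")
  if (!all(raw$source %in% c("ligand", "ppi_hotspot")))
    stop_vb("binding source must be 'ligand' or 'ppi_hotspot'")
  raw
}

#' Restrict a cohort to patients whose panel covers a gene
#'
#' Gene-level analyses include only patients sequenced with a panel that
#' targets the gene of interest; order is preserved.
#'
#' @param patients Patient data.frame with a `panel_id` column.
#' @param coverage Named list from [read_panel_table()].
#' @param gene Gene symbol.
#' @return Subset of `patients`.
#' @export
filter_panel <- function(patients, coverage, gene) {
  unknown <- setdiff(unique(patients$panel_id), names(coverage))
  if (length(unknown))
    stop_vb("unknown panel_id(s): %s", paste(unknown, collapse = ", "))
  covered <- vapply(patients$panel_id, function(p) gene %in% coverage[[p]],
                    logical(1))
  if (!any(covered)) warning(sprintf("no panel covers gene %s", gene))
  patients[covered, , drop = FALSE]
}

#' Describe a VEP's orientation and calibration mode
#'
#' @param name Method name.
#' @param orientation "higher_pathogenic" or "lower_pathogenic".
#' @param calibration_mode One of "builtin_classes", "qvalue_threshold",
#'   "learned_cutoff", "class_selection".
#' @param threshold Optional fixed threshold.
#' @param class_map Optional named vector mapping builtin labels to
#'   "pathogenic"/"benign"/"uncertain".
#' @return A `method_spec` object.
#' @export
method_spec <- function(name,
                        orientation = c("higher_pathogenic",
                                        "lower_pathogenic"),
                        calibration_mode = c("learned_cutoff",
                                             "builtin_classes",
                                             "qvalue_threshold",
                                             "class_selection"),
                        threshold = NULL, class_map = NULL) {
  orientation <- match.arg(orientation)
  calibration_mode <- match.arg(calibration_mode)
  if (calibration_mode == "builtin_classes" && is.null(class_map))
    stop_vb("builtin_classes requires a class_map")
  structure(list(name = name, orientation = orientation,
                 calibration_mode = calibration_mode,
                 threshold = threshold, class_map = class_map),
            class = "method_spec")
}

#' @export
print.method_spec <- function(x, ...) {
  cat(sprintf("<method_spec> %s (%s, %s)\n", x$name, x$orientation,
              x$calibration_mode))
  invisible(x)
}
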