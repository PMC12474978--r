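# Synthetic cohort generator: panel-censored mutation tables with OG/TSG
# gene roles, class-conditional VEP scores, binding-site enrichment among
# latent drivers, confounded survival with gene-level hazard effects, and
# within-pathway mutual exclusivity -- everything the four benchmarks
# assume, with the latent truth recorded for parameter-recovery tests.

#' Default gene panel for the simulated cohort
#'
#' NSCLC-like gene set: per-patient mutation probability, the fraction of
#' mutations that are known (OncoKB-annotated) oncogenic, the latent
#' driver fraction among VUSs, and true log hazard ratios per carrier
#' class.
#'
#' @return data.frame(symbol, role, mut_prob, onc_frac, path_vus_frac,
#'   loghr_oncogenic, loghr_pathvus, loghr_benignvus).
#' @export
default_genes <- function() {
  data.frame(
    symbol = c("KEAP1", "STK11", "SMARCA4", "EGFR", "KRAS", "NFE2L2",
               "CUL3", "NF1", "ERBB4", "IRS2", "TP53", "ATM"),
    role = c("TSG", "TSG", "TSG", "OG", "OG", "OG", "TSG", "TSG", "OG",
             "OG", "TSG", "TSG"),
    mut_prob = c(0.12, 0.10, 0.08, 0.15, 0.25, 0.04, 0.03, 0.08, 0.05,
                 0.03, 0.45, 0.10),
    onc_frac = c(0.35, 0.40, 0.30, 0.60, 0.70, 0.50, 0.30, 0.30, 0.20,
                 0.20, 0.80, 0.30),
    path_vus_frac = c(0.50, 0.40, 0.40, 0.30, 0.20, 0.30, 0.30, 0.40,
                      0.30, 0.30, 0.30, 0.40),
    loghr_oncogenic = c(log(2), 0.4, 0.4, 0, 0.15, 0, 0, 0, 0, 0, 0.2, 0),
    loghr_pathvus = c(log(2), 0.4, 0.4, 0, 0.15, 0, 0, 0, 0, 0, 0.2, 0),
    loghr_benignvus = rep(0, 12),
    stringsAsFactors = FALSE)
}

#' Default simulated VEP methods
#'
#' Class-conditional Beta score distributions on [0, 1] (bounded scores
#' resemble most VEP outputs); "lower_pathogenic" methods reflect the
#' score so one sampler serves both orientations. Separations emulate a
#' strong structure-aware method, a mid ensemble, a weaker
#' evolution-only method, and a negatively oriented log-likelihood-style
#' method.
#'
#' @return data.frame(name, orientation, benign_a, benign_b, path_a,
#'   path_b, miss_rate).
#' @export
default_methods <- function() {
  data.frame(
    name = c("deep_struct", "ens_sup", "evo_only", "llr_neg"),
    orientation = c("higher_pathogenic", "higher_pathogenic",
                    "higher_pathogenic", "lower_pathogenic"),
    benign_a = c(2, 2, 3, 2), benign_b = c(8, 6, 5, 7),
    path_a = c(8, 6, 5, 7), path_b = c(2, 3, 4, 2),
    miss_rate = c(0.05, 0.10, 0.10, 0.15),
    stringsAsFactors = FALSE)
}

#' Default trinucleotide-change profile (smoking-exposed lung-like)
#'
#' C>A transversions dominate with a C>T component, flank preferences
#' mild; pyrimidine-centered SBS96 convention.
#'
#' @return A `context_profile`.
#' @export
default_context_profile <- function() {
  cats <- sbs96_categories()
  w <- rep(1, 96)
  w[cats$ref == "C" & cats$alt == "A"] <- 6
  w[cats$ref == "C" & cats$alt == "T"] <- 4
  w[cats$ref == "T" & cats$alt == "C"] <- 2
  cats$prob <- w / sum(w)
  structure(cats, class = c("context_profile", "data.frame"),
            tumor_type = "synthetic_lung", n_source_mutations = NA_integer_)
}

#' Simulation configuration
#'
#' Defaults define the study conditions for the whole test battery:
#' a confounded NSCLC-like cohort of 2000 patients with a true hazard
#' ratio of 2.0 on KEAP1 pathogenic mutations, binding-site enrichment
#' odds ratio 5 among latent drivers, and within-pathway mutual
#' exclusivity.
#'
#' @param n_patients Cohort size (default 2000).
#' @param seed Integer seed; identical config + seed gives identical
#'   output.
#' @param genes Gene table as [default_genes()].
#' @param methods Method table as [default_methods()].
#' @param pathways Named list: pathway -> list(genes, excl_or); excl_or is
#'   the target 2x2 odds ratio of driver co-occurrence (1 = independence).
#' @param binding_enrichment_or Odds ratio of latent drivers hitting
#'   binding residues (default 5).
#' @param binding_frac Fraction of residues that are binding sites.
#' @param protein_length Residues per gene product.
#' @param context_profile SBS96 profile of mutation contexts.
#' @param confounding list(covariate, mut_logodds, loghr): the covariate
#'   shifts both mutation odds and hazard, confounding naive gene-survival
#'   associations.
#' @param baseline_hazard Events per month at covariate baseline.
#' @param censor_horizon Administrative censoring (months from
#'   diagnosis).
#' @param entry_window Sequencing (cohort entry) uniform on [0, window]
#'   months after diagnosis.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_patients = 2000, seed = 1,
                       genes = default_genes(),
                       methods = default_methods(),
                       pathways = list(
                         NRF2 = list(genes = c("KEAP1", "NFE2L2", "CUL3"),
                                     excl_or = 0.2),
                         RTK_RAS = list(genes = c("EGFR", "KRAS", "NF1",
                                                  "ERBB4", "IRS2"),
                                        excl_or = 0.3),
                         TP53_PW = list(genes = c("TP53", "ATM"),
                                        excl_or = 0.5)),
                       binding_enrichment_or = 5,
                       binding_frac = 0.15,
                       protein_length = 500,
                       context_profile = default_context_profile(),
                       confounding = list(covariate = "smoking",
                                          mut_logodds = 1.2, loghr = 0.8),
                       baseline_hazard = 0.015,
                       censor_horizon = 60,
                       entry_window = 12) {
  stopifnot(n_patients >= 1,
            all(genes$mut_prob >= 0 & genes$mut_prob <= 1),
            all(genes$path_vus_frac >= 0 & genes$path_vus_frac <= 1))
  validate_profile(context_profile)
  pw_genes <- unlist(lapply(pathways, `[[`, "genes"))
  missing_g <- setdiff(pw_genes, genes$symbol)
  if (length(missing_g))
    stop_vb("pathway gene(s) absent from gene list: %s",
            paste(missing_g, collapse = ", "))
  structure(as.list(environment()), class = "sim_config")
}

AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
         "F", "P", "S", "T", "W", "Y", "V")

# Deterministic HGVS p. short string per (gene, residue) so recurrent
# occurrences of a residue share one variant identity.
residue_pchange <- function(res) {
  ref <- AA1[(res %% 20) + 1]
  alt <- AA1[((res * 7 + 3) %% 20) + 1]
  alt[alt == ref] <- AA1[((res[alt == ref] * 7 + 4) %% 20) + 1]
  paste0("p.", ref, res, alt)
}

# Split binding residues between driver and passenger sets so the
# driver-vs-passenger binding odds ratio hits the target exactly (up to
# integer rounding).
solve_binding_split <- function(n_driver, n_passenger, n_binding, or) {
  f <- function(bd) {
    bp <- n_binding - bd
    (bd / (n_driver - bd)) / (bp / (n_passenger - bp)) - or
  }
  lo <- max(1, n_binding - n_passenger + 1)
  hi <- min(n_driver - 1, n_binding - 1)
  bd <- tryCatch(uniroot(f, c(lo, hi))$root, error = function(e) NA)
  if (is.na(bd)) bd <- n_binding * n_driver / (n_driver + n_passenger)
  round(bd)
}

#' @importFrom stats uniroot plogis qlogis
NULL

#' Latent variant universe for the simulated genes
#'
#' For each gene: known-oncogenic hotspot residues, latent-driver VUS
#' residues, passenger VUS residues, and the binding-residue set arranged
#' so latent drivers (hotspots included) hit binding residues with the
#' configured odds ratio relative to passengers.
#'
#' @param config A [sim_config()].
#' @return List: variants (data.frame gene, residue, protein_change, key,
#'   class, binding), binding_map (data.frame gene, residue, source).
#' @export
generate_variant_universe <- function(config) {
  with_seed(derive_seed(config$seed, "universe"), {
    n_known <- 8L; n_latent <- 32L
    L <- config$protein_length
    n_driver <- n_known + n_latent
    n_pass <- L - n_driver
    n_bind <- round(config$binding_frac * L)
    bd <- solve_binding_split(n_driver, n_pass, n_bind,
                              config$binding_enrichment_or)
    rows <- lapply(config$genes$symbol, function(g) {
      res <- sample.int(L)
      driver_res <- res[seq_len(n_driver)]
      pass_res <- res[n_driver + seq_len(n_pass)]
      bind_res <- c(sample(driver_res, bd),
                    sample(pass_res, n_bind - bd))
      known <- driver_res[seq_len(n_known)]
      latent <- driver_res[n_known + seq_len(n_latent)]
      cls <- c(rep("oncogenic", n_known), rep("driver_vus", n_latent),
               rep("passenger_vus", n_pass))
      rr <- c(known, latent, pass_res)
      data.frame(gene = g, residue = rr,
                 protein_change = residue_pchange(rr),
                 class = cls, binding = rr %in% bind_res,
                 stringsAsFactors = FALSE)
    })
    variants <- do.call(rbind, rows)
    variants$key <- variant_key(variants$gene, variants$protein_change)
    bind <- variants[variants$binding, c("gene", "residue")]
    bind$source <- rep_len(c("ligand", "ppi_hotspot"), nrow(bind))
    list(variants = variants, binding_map = bind)
  })
}

#' Draw i.i.d. trinucleotide contexts from a 96-category profile
#'
#' @param config A [sim_config()] (its context_profile is used).
#' @param n Number of draws.
#' @param seed Integer seed.
#' @return data.frame(label, context3, ref, alt).
#' @export
generate_mutation_contexts <- function(config, n, seed = config$seed) {
  simulate_neutral_variants(config$context_profile, n, seed = seed)
}

# Draw per-patient, per-gene mutation status. Oncogenic and VUS
# mutations are drawn independently within a gene (tumors may carry
# both), so no structural within-gene exclusivity is induced. Pathway
# exclusivity comes from rejection sampling: a configuration is accepted
# with probability prod_pw or^(choose(n_drivers_in_pw, 2)), which under
# independence yields a pairwise driver co-occurrence odds ratio equal
# to the target. Returns list(onc = logical n x G, vus = integer n x G
# with 0 none / 2 latent driver / 3 passenger).
draw_gene_status <- function(config, z) {
  n <- length(z)
  G <- nrow(config$genes)
  draw_block <- function(idx) {
    onc <- matrix(FALSE, length(idx), G)
    vus <- matrix(0L, length(idx), G)
    for (j in seq_len(G)) {
      gg <- config$genes[j, ]
      shift <- config$confounding$mut_logodds * z[idx]
      p_onc <- plogis(qlogis(pmax(gg$mut_prob * gg$onc_frac, 1e-12)) +
                        shift)
      p_vus <- plogis(qlogis(pmax(gg$mut_prob * (1 - gg$onc_frac),
                                  1e-12)) + shift)
      onc[, j] <- rbinom(length(idx), 1, p_onc) == 1
      has_vus <- rbinom(length(idx), 1, p_vus) == 1
      vus[has_vus, j] <- ifelse(
        rbinom(sum(has_vus), 1, gg$path_vus_frac) == 1, 2L, 3L)
    }
    list(onc = onc, vus = vus)
  }
  accept_prob <- function(st) {
    # driver units: every driver mutation counts, so redundancy between
    # an oncogenic mutation and a latent-driver VUS of the same gene is
    # thinned like any cross-gene pair
    p <- rep(1, nrow(st$onc))
    for (pw in config$pathways) {
      jj <- match(pw$genes, config$genes$symbol)
      d <- rowSums(st$onc[, jj, drop = FALSE]) +
        rowSums(st$vus[, jj, drop = FALSE] == 2L)
      p <- p * pw$excl_or^(choose(d, 2))
    }
    p
  }
  st <- draw_block(seq_len(n))
  active <- which(runif(n) > accept_prob(st))
  tries <- 0
  while (length(active) && tries < 200) {
    blk <- draw_block(active)
    st$onc[active, ] <- blk$onc
    st$vus[active, ] <- blk$vus
    sub <- list(onc = st$onc[active, , drop = FALSE],
                vus = st$vus[active, , drop = FALSE])
    active <- active[runif(length(active)) > accept_prob(sub)]
    tries <- tries + 1
  }
  st
}

#' Generate a full synthetic cohort
#'
#' Produces patients (covariates, confounded left-truncated survival),
#' mutations (MAF-style with OncoKB classes and trinucleotide contexts),
#' class-conditional VEP scores, a binding-residue map, pathway specs and
#' the latent truth record. Survival times follow a proportional-hazards
#' exponential model: per-patient log hazard is the sum of gene-class
#' effects plus the confounder effect; patients enter the risk set at
#' sequencing, and only patients alive at entry are observed (proper
#' left-truncation sampling keeps exactly n_patients).
#'
#' @param config A [sim_config()].
#' @return A `vb_cohort` list: patients, mutations, scores (matrix),
#'   binding_map, pathways (named list of gene vectors), coverage,
#'   truth, config.
#' @export
generate_cohort <- function(config) {
  uni <- generate_variant_universe(config)
  G <- nrow(config$genes)
  out <- with_seed(derive_seed(config$seed, "cohort"), {
    n <- config$n_patients
    acc_pat <- NULL; acc_onc <- NULL; acc_vus <- NULL
    while (is.null(acc_pat) || nrow(acc_pat) < n) {
      m <- n - if (is.null(acc_pat)) 0 else nrow(acc_pat)
      m <- max(m, 50)
      smoking <- sample(c("ever", "never"), m, replace = TRUE)
      z <- as.integer(smoking == "ever")
      st <- draw_gene_status(config, z)
      lp <- as.numeric(
        st$onc %*% config$genes$loghr_oncogenic +
          (st$vus == 2L) %*% config$genes$loghr_pathvus +
          (st$vus == 3L) %*% config$genes$loghr_benignvus) +
        config$confounding$loghr * z
      t_death <- rexp(m, rate = config$baseline_hazard * exp(lp))
      t_entry <- runif(m, 0, config$entry_window)
      event <- as.integer(t_death <= config$censor_horizon)
      t_end <- pmin(t_death, config$censor_horizon)
      keep <- t_end > t_entry
      pat <- data.frame(
        smoking = smoking, z = z, t_entry = t_entry, t_end = t_end,
        event = event, lp = lp, stringsAsFactors = FALSE)[keep, ,
                                                          drop = FALSE]
      acc_pat <- rbind(acc_pat, pat)
      acc_onc <- rbind(acc_onc, st$onc[keep, , drop = FALSE])
      acc_vus <- rbind(acc_vus, st$vus[keep, , drop = FALSE])
    }
    acc_pat <- acc_pat[seq_len(n), , drop = FALSE]
    acc_onc <- acc_onc[seq_len(n), , drop = FALSE]
    acc_vus <- acc_vus[seq_len(n), , drop = FALSE]
    pid <- sprintf("P%05d", seq_len(n))
    n_mut <- rowSums(acc_onc) + rowSums(acc_vus > 0)
    patients <- data.frame(
      patient_id = pid, cohort_id = "SYN",
      panel_id = sample(c("panel_A", "panel_B"), n, replace = TRUE,
                        prob = c(0.8, 0.2)),
      age = round(rnorm(n, 66, 10), 1),
      sex = sample(c("F", "M"), n, replace = TRUE),
      race = sample(c("white", "black", "asian", "other"), n,
                    replace = TRUE, prob = c(0.6, 0.15, 0.15, 0.1)),
      histology = sample(c("adeno", "squamous", "other"), n,
                         replace = TRUE, prob = c(0.6, 0.25, 0.15)),
      stage = sample(c("I", "II", "III", "IV"), n, replace = TRUE,
                     prob = c(0.2, 0.15, 0.2, 0.45)),
      smoking = acc_pat$smoking,
      prior_treatment = rbinom(n, 1, 0.3) == 1,
      metastasis = rbinom(n, 1, 0.4) == 1,
      tmb = round(exp(rnorm(n, log(4) + 0.4 * acc_pat$z, 0.7)) +
                    0.3 * n_mut, 2),
      msi_score = round(abs(rnorm(n, 0, 4)), 2),
      t_dx = 0, t_entry = acc_pat$t_entry, t_end = acc_pat$t_end,
      event = acc_pat$event, stringsAsFactors = FALSE)
    # occurrences: one row per carried oncogenic mutation and one per
    # carried VUS; residue drawn from the class-matched universe set
    occ_o <- which(acc_onc, arr.ind = TRUE)
    occ_v <- which(acc_vus > 0, arr.ind = TRUE)
    occ <- rbind(occ_o, occ_v)
    occ_gene <- config$genes$symbol[occ[, 2]]
    occ_class <- c(rep("oncogenic", nrow(occ_o)),
                   c("driver_vus", "passenger_vus")[acc_vus[occ_v] - 1L])
    vu <- uni$variants
    pick <- vapply(seq_len(nrow(occ)), function(k) {
      pool <- which(vu$gene == occ_gene[k] & vu$class == occ_class[k])
      pool[sample.int(length(pool), 1)]
    }, integer(1))
    ctx <- simulate_neutral_variants(config$context_profile, nrow(vu),
                                     seed = derive_seed(config$seed,
                                                        "contexts"))
    flip <- rbinom(nrow(vu), 1, 0.5) == 1
    v_ctx <- ctx$context3; v_ref <- ctx$ref; v_alt <- ctx$alt
    v_ctx[flip] <- revcomp3(v_ctx[flip])
    v_ref[flip] <- unname(COMPLEMENT[ctx$ref[flip]])
    v_alt[flip] <- unname(COMPLEMENT[ctx$alt[flip]])
    v_chrom <- paste0("chr", (match(vu$gene, config$genes$symbol) %% 22) + 1)
    v_pos <- 1e6 + seq_len(nrow(vu)) * 100
    mutations <- data.frame(
      patient_id = pid[occ[, 1]],
      sample_id = paste0(pid[occ[, 1]], "-T1"),
      gene = occ_gene,
      protein_change = vu$protein_change[pick],
      chrom = v_chrom[pick], pos = v_pos[pick],
      ref = v_ref[pick], alt = v_alt[pick], context3 = v_ctx[pick],
      is_missense = TRUE,
      oncokb_class = ifelse(occ_class == "oncogenic", "oncogenic", "vus"),
      stringsAsFactors = FALSE)
    list(patients = patients, mutations = mutations, onc = acc_onc,
         vus = acc_vus, lp = acc_pat$lp)
  })
  # scores over the observed unique variants
  keys_obs <- unique(variant_key(out$mutations$gene,
                                 out$mutations$protein_change))
  vu <- uni$variants
  is_driver <- setNames(vu$class %in% c("oncogenic", "driver_vus"), vu$key)
  scores <- with_seed(derive_seed(config$seed, "scores"), {
    m <- matrix(NA_real_, length(keys_obs), nrow(config$methods),
                dimnames = list(keys_obs, config$methods$name))
    drv <- is_driver[keys_obs]
    for (j in seq_len(nrow(config$methods))) {
      mm <- config$methods[j, ]
      s <- ifelse(drv, rbeta(length(keys_obs), mm$path_a, mm$path_b),
                  rbeta(length(keys_obs), mm$benign_a, mm$benign_b))
      if (mm$orientation == "lower_pathogenic") s <- 1 - s
      s[runif(length(s)) < mm$miss_rate] <- NA
      m[, j] <- s
    }
    m
  })
  pathways <- lapply(config$pathways, `[[`, "genes")
  coverage <- list(panel_A = config$genes$symbol,
                   panel_B = setdiff(config$genes$symbol, "IRS2"))
  truth <- list(
    variant_class = setNames(ifelse(is_driver, "driver", "passenger"),
                             vu$key),
    variant_table = vu,
    gene_effects = config$genes[, c("symbol", "loghr_oncogenic",
                                    "loghr_pathvus", "loghr_benignvus")],
    onc = out$onc, vus = out$vus,
    driver = out$onc | out$vus == 2L,
    patient_lp = out$lp)
  truth$patient_confounder <- as.integer(out$patients$smoking == "ever")
  structure(list(patients = out$patients, mutations = out$mutations,
                 scores = scores, binding_map = uni$binding_map,
                 pathways = pathways, coverage = coverage, truth = truth,
                 config = config),
            class = "vb_cohort")
}

#' @export
print.vb_cohort <- function(x, ...) {
  cat(sprintf("<vb_cohort> %d patients, %d mutations (%d unique variants), %d methods, %d pathways\n",
              nrow(x$patients), nrow(x$mutations), nrow(x$scores),
              ncol(x$scores), length(x$pathways)))
  invisible(x)
}

#' Analytic AUROC of two Beta score distributions
#'
#' P(X_path > X_benign) for independent Beta draws, by numerical
#' integration; used to check the generator's configured separations.
#'
#' @param path_a,path_b,benign_a,benign_b Beta parameters.
#' @return AUROC in [0, 1].
#' @export
beta_auroc <- function(path_a, path_b, benign_a, benign_b) {
  integrate(function(x)
    dbeta(x, path_a, path_b) * pbeta(x, benign_a, benign_b),
    0, 1, rel.tol = 1e-10)$value
}

#' @importFrom stats dbeta pbeta
NULL

#' Write the cohort as the TSV dialects the readers accept
#'
#' @param cohort A `vb_cohort`.
#' @param dir Output directory (created if absent).
#' @return Named vector of file paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(mutations = file.path(dir, "mutations.tsv"),
             clinical = file.path(dir, "clinical.tsv"),
             scores = file.path(dir, "scores.tsv"),
             panels = file.path(dir, "panels.tsv"),
             pathways = file.path(dir, "pathways.tsv"),
             binding = file.path(dir, "binding.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_mutation_table(cohort$mutations, paths["mutations"])
  write.table(cohort$patients, paths["clinical"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  sk <- do.call(rbind, strsplit(rownames(cohort$scores), ":p\\."))
  sc <- data.frame(gene = sk[, 1], protein_change = paste0("p.", sk[, 2]),
                   cohort$scores, check.names = FALSE)
  write.table(sc, paths["scores"], sep = "\t", quote = FALSE,
              row.names = FALSE, na = ".")
  write.table(data.frame(
    panel_id = rep(names(cohort$coverage), lengths(cohort$coverage)),
    gene = unlist(cohort$coverage)), paths["panels"], sep = "\t",
    quote = FALSE, row.names = FALSE)
  write.table(data.frame(
    pathway = rep(names(cohort$pathways), lengths(cohort$pathways)),
    gene = unlist(cohort$pathways)), paths["pathways"], sep = "\t",
    quote = FALSE, row.names = FALSE)
  write.table(cohort$binding_map, paths["binding"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(data.frame(key = names(cohort$truth$variant_class),
                         class = cohort$truth$variant_class),
              paths["truth"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}

#' Purpose-built study configurations for parameter-recovery checks
#'
#' `recovery_config` defines the confounded survival-recovery study: one
#' gene whose pathogenic VUSs carry a true hazard ratio of 2.0, with
#' smoking shifting both mutation odds (+1.2 log odds) and hazard (+0.8
#' log hazard) so the naive carrier-vs-none Cox estimate is biased while
#' the IPTW estimate is not. `rr_config` defines the RR-metric coverage
#' study: one gene whose VUSs split evenly into latent drivers (HR 2.0)
#' and passengers (HR 1.0), no confounding, so the true RR is 2.0.
#' `mutex_sim_config` defines a three-gene pathway of commonly altered
#' genes for mutual-exclusivity calibration at a chosen target odds
#' ratio.
#'
#' @param seed Integer seed.
#' @param n_patients Cohort size.
#' @param excl_or Target driver co-occurrence odds ratio
#'   (mutex_sim_config).
#' @return A [sim_config()].
#' @export
recovery_config <- function(seed, n_patients = 2000) {
  sim_config(
    n_patients = n_patients, seed = seed,
    genes = data.frame(symbol = "GENE1", role = "TSG", mut_prob = 0.35,
                       onc_frac = 0, path_vus_frac = 1,
                       loghr_oncogenic = log(2), loghr_pathvus = log(2),
                       loghr_benignvus = 0, stringsAsFactors = FALSE),
    pathways = list(),
    confounding = list(covariate = "smoking", mut_logodds = 1.5,
                       loghr = 1.0))
}

#' @rdname recovery_config
#' @export
rr_config <- function(seed, n_patients = 800) {
  sim_config(
    n_patients = n_patients, seed = seed,
    genes = data.frame(symbol = "GENE1", role = "TSG", mut_prob = 0.40,
                       onc_frac = 0, path_vus_frac = 0.5,
                       loghr_oncogenic = log(2), loghr_pathvus = log(2),
                       loghr_benignvus = 0, stringsAsFactors = FALSE),
    pathways = list(),
    confounding = list(covariate = "smoking", mut_logodds = 0,
                       loghr = 0))
}

#' @rdname recovery_config
#' @export
mutex_sim_config <- function(seed, excl_or = 1, n_patients = 1000) {
  genes <- data.frame(symbol = c("G1", "G2", "G3"), role = "OG",
                      mut_prob = 0.25, onc_frac = 0.5,
                      path_vus_frac = 0.5, loghr_oncogenic = 0,
                      loghr_pathvus = 0, loghr_benignvus = 0,
                      stringsAsFactors = FALSE)
  sim_config(n_patients = n_patients, seed = seed, genes = genes,
             pathways = list(PW = list(genes = genes$symbol,
                                       excl_or = excl_or)),
             confounding = list(covariate = "smoking", mut_logodds = 0,
                                loghr = 0))
}

#' Truth-based (perfect) VUS classification for a simulated cohort
#'
#' Maps every latent driver VUS to "pathogenic" and every passenger VUS
#' to "benign" using the generator's truth record; the oracle classifier
#' for generator-recovery tests.
#'
#' @param cohort A `vb_cohort`.
#' @return Named character vector (variant key -> class).
#' @export
truth_classifier <- function(cohort) {
  vu <- cohort$truth$variant_table
  vus <- vu[vu$class != "oncogenic", ]
  setNames(ifelse(vus$class == "driver_vus", "pathogenic", "benign"),
           vus$key)
}
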