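# vepbench

Benchmarks for computational variant effect predictors (VEPs) against
the statistical structure of real-world cancer cohorts.

Most somatic mutations detected by tumor panel sequencing are variants
of unknown significance (VUSs). VEPs such as structure-aware deep
learning models or conservation-based scores can reclassify VUSs as
pathogenic or benign — but whether those calls are *clinically
meaningful* cannot be read off a ClinVar AUROC. This package implements
four cohort-level validation benchmarks for anyone (computational
oncology groups, methodologists building or choosing VEPs) who wants to
test reclassified calls against the behavior known drivers exhibit in
patient data:

1. **Driver rediscovery** — AUROC of raw scores on known oncogenic vs
   benign variants, at mutation level (each unique variant once) and
   population level (each occurrence once), with DeLong 95% CIs and
   FDR-corrected paired DeLong comparisons between methods.
2. **Binding-residue enrichment** — `OR_binding`: the pooled odds ratio
   of reclassified-pathogenic vs reclassified-benign VUSs hitting
   ligand-binding residues or protein-interaction hotspots, with exact
   two-sided Fisher p-values by hypergeometric enumeration and Woolf
   CIs (Haldane–Anscombe correction at zero cells).
3. **Survival** — per-gene strata (oncogenic / reclassified pathogenic
   / reclassified benign / no mutation), stabilized IPTW from baseline
   covariates with SMD balance diagnostics, weighted Cox PH models from
   diagnosis left-truncated at sequencing (robust variance), weighted
   Kaplan–Meier curves, and the relative risk of survival
   `RR = HR(pathogenic vs none) / HR(benign vs none)` with a
   patient-level bootstrap CI. Includes double-mutant strata and
   two-stage discovery/confirmation FDR logic.
4. **Pathway mutual exclusivity** — one-vs-all Fisher battery per
   (gene, pathway, method), significant when logOR < 0 and BH q ≤ 0.1;
   pathway-level exclusivity rates; `OR_mutex`; TMB-adjusted logistic
   regression separating exclusivity from mutational-burden artifacts.

Around the benchmarks: score calibration exactly as predictors ship
(built-in class maps, class-stringency selection, BH q-value rules, and
Youden-type cutpoints with a median-of-ties rule and boundary-inclusive
thresholds), an SBS96 trinucleotide-context neutral-variant simulator
for tumor-matched negative controls, a random-forest score ensemble
with gene-holdout cross-validation, and a synthetic cohort generator
with recorded latent truth (class-conditional scores, binding
enrichment, confounded left-truncated survival, within-pathway
exclusivity) so the whole pipeline is testable without access-gated
patient data.

## Worked example

```r
library(vepbench)
cohort <- generate_cohort(sim_config(n_patients = 2000, seed = 1))
res <- run_pipeline(cohort, seed = 1)
```

The default synthetic cohort is NSCLC-like: 2000 patients, 12 genes
with OG/TSG roles, four simulated VEPs of differing quality, a true
KEAP1 pathogenic-VUS hazard ratio of 2.0 confounded by smoking, a
binding-enrichment odds ratio of 5 among latent drivers, and
within-pathway driver exclusivity. The run prints:

```
> res$roc
       method stratum      level auroc ci_low ci_high n_pos n_neg
1 deep_struct     all population 0.999  0.999   0.999  2214  2271
2     ens_sup     all population 0.972  0.968   0.976  1974  2271
3    evo_only     all population 0.824  0.812   0.837  2028  2271
4     llr_neg     all population 0.999  0.998   0.999  1695  2271

> res$binding$deep_struct
<enrichment> OR_binding OR 5.036 [3.763, 6.739], p = 3.92e-26 (a=115 b=160 c=160 d=1121)

> res$survival$deep_struct$cox_pathogenic
<cox_result> KEAP1 reclassified_pathogenic_vs_none: HR 1.745 [1.391, 2.190],
             p = 1.54e-06 (n = 111 vs 1632, 1288 events, IPTW)

> res$survival$deep_struct$rr
<rr_result> RR 1.470 [1.091, 1.995] = 1.745 / 1.187
```

Reading this: the strong simulated methods (`deep_struct`, and
`llr_neg` after orientation handling) rediscover known drivers almost
perfectly at population level while the conservation-only method lags
(AUROC 0.82); reclassified-pathogenic VUSs are ~5× enriched at binding
residues, matching the generator's configured enrichment; KEAP1
pathogenic-VUS carriers show an IPTW hazard ratio of 1.75 against
no-mutation patients while benign-VUS carriers sit near 1.19, giving
RR = 1.47 with a bootstrap CI excluding 1 — the method's pathogenic
calls carry outcome information its benign calls do not.
`res$mutex_rates` adds the per-pathway exclusivity rates (e.g. NRF2
0.33: one of the three pathway genes shows significant mutual
exclusivity for this method at q ≤ 0.1).

## Layout

* `R/core_model.R` — domain types, MAF/clinical/score/panel/pathway/
  binding readers, TMB/MSI flags, panel filtering
* `R/synthetic_cohort.R` — generator and study configurations
* `R/neutral_variants.R` — SBS96 profiles and neutral-variant simulation
* `R/calibration.R` — cutpoints, class selection, BH, classification
* `R/driver_rediscovery.R` — AUROC/DeLong, comparisons, per-gene TPR
* `R/binding_enrichment.R` — exact 2×2 machinery, `OR_binding`
* `R/survival_benchmark.R` — strata, IPTW, weighted Cox/KM, RR,
  double mutants, discovery/confirmation
* `R/pathway_mutex.R` — mutex battery, pathway rates, `OR_mutex`,
  TMB-adjusted logistic
* `R/ensemble_rf.R` — preprocessing, splits, gene-holdout CV, forest
* `R/pipeline.R` — `run_pipeline()` orchestration and TSV/JSON output

The methods vignette (`vignettes/vep-benchmarking.Rmd`) documents the
statistical choices, the generator's assumptions, and what the
synthetic results do and do not establish about real data.
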