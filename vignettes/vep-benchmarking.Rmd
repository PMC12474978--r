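---
title: "Benchmarking variant effect predictors against real-world cohort structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking variant effect predictors against real-world cohort structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vepbench)
options(vepbench.verbose = FALSE)
```

## The problem

Most somatic mutations found by tumor panel sequencing are variants of
unknown significance (VUSs): they have no curated oncogenic or benign
annotation. Computational variant effect predictors (VEPs) score every
missense change, and a calibrated threshold turns those scores into
"reclassified pathogenic" and "reclassified benign" calls for VUSs. The
question this package addresses is how to tell whether those calls mean
anything *clinically*, without running functional assays.

The answer implemented here is a battery of four benchmarks that ask
whether reclassified calls behave like known driver mutations do in
real cohorts:

1. **Driver rediscovery.** Can the raw scores separate known oncogenic
   mutations from benign variants? Measured by AUROC with DeLong
   confidence intervals, at two instance weightings: *mutation level*
   (each unique variant once) and *population level* (each occurrence
   once, reflecting real-world allele frequencies). Methods are compared
   by paired DeLong tests with Benjamini–Hochberg (BH) correction.
2. **Binding-residue enrichment.** Pathogenic mutations often disrupt
   ligand-binding residues or protein–protein-interaction hotspots.
   `OR_binding` is the pooled odds ratio of reclassified-pathogenic vs
   reclassified-benign VUSs falling on binding residues.
3. **Survival.** Patients are stratified per gene into carriers of known
   oncogenic mutations, reclassified-pathogenic VUSs,
   reclassified-benign VUSs, or no mutation. Overall survival is
   compared by Cox proportional-hazards models measured from diagnosis
   and left-truncated at sequencing (cohort entry), weighted by
   stabilized inverse-probability-of-treatment weights (IPTW) estimated
   from baseline covariates. The headline metric is
   `RR = HR(pathogenic vs none) / HR(benign vs none)`: a method that
   separates outcome-relevant VUSs from inert ones has RR > 1.
4. **Pathway mutual exclusivity.** Real drivers in the same signaling
   pathway rarely co-occur in one tumor. A one-vs-all Fisher battery
   tests whether reclassified-pathogenic carriers of each gene avoid
   tumors with known oncogenic mutations in the gene's pathway
   (significant when logOR < 0 and BH q ≤ 0.1), summarized per pathway
   as the fraction of genes with a significant test, plus a TMB-adjusted
   logistic regression to rule out mutational-burden artifacts.

A random-forest ensemble over all per-method scores (z-scored, 75:25
stratified split, mtry tuned by 5-fold or gene-holdout CV) checks
whether the methods carry complementary information.

## Calibration modes

Raw scores become calls through one of four modes, mirroring how
published predictors are distributed:

* `builtin_classes` — the provider ships labels; a class map sends them
  to pathogenic/benign/uncertain. Uncertain calls are excluded from both
  reclassified sets downstream, since reclassification is two-sided.
* `class_selection` — providers shipping labels at several uncertainty
  strata; the stratum with the highest AUROC on known classes is chosen,
  ties resolved toward the stratum excluding fewest variants.
* `qvalue_threshold` — providers shipping p-values against a background
  model; BH q ≤ 0.05 (boundary inclusive) is pathogenic.
* `learned_cutoff` — a Youden-type cutpoint: every unique observed score
  is a candidate threshold, the objective is sensitivity + specificity,
  and when several thresholds tie at the maximum their *median* is used.
  Classification is boundary-inclusive on the pathogenic side (score ≥ t
  for positively oriented methods, ≤ t for negatively oriented ones).
  Cutpoints are relearned per dataset.

Candidate thresholds are the observed scores themselves, not midpoints:
the boundary rules above are stated on observed values, and midpoint
thresholds would be untestable against them. The cutpoint scan weights
instances at mutation level by default (an option exposes population
weighting); this choice is documented as an assumption.

## Statistical machinery and numerical choices

**Exact 2×2 tests.** Two-sided Fisher p-values are computed by direct
hypergeometric enumeration: all tables with the observed margins whose
probability does not exceed the observed table's (with a 1e-7 relative
guard against floating-point ties) are summed. The odds ratio reported
alongside is the *sample* OR (ad)/(bc) with the Haldane–Anscombe 0.5
correction applied to all cells when any cell is zero — the exact p is
never corrected — and a Woolf log-normal 95% CI. The correction keeps
the mutual-exclusivity sign rule (logOR < 0) well defined at zero
cells. `stats::fisher.test` reports a conditional-MLE OR instead, which
is why the test suite uses it only as an independent cross-check on the
p-value.

**AUROC and DeLong.** AUROC is the Mann–Whitney estimator with ties
counted ½, computed via midranks. Variance uses DeLong structural
components; CIs are normal-approximation, clipped to [0, 1]. Degenerate
variance (identical or perfectly separating scores) collapses the CI to
a point and is flagged; a paired comparison of identical score vectors
reports p = 1, and degenerate-variance comparisons with nonzero
difference report p = NA rather than fabricated significance. Negative
upsampling (sampling benign variants with replacement to match the
positive class size) balances classes before ROC analysis; AUROC is
invariant to this in expectation, which the suite verifies.

**IPTW.** Propensities come from a main-effects logistic model on the
baseline covariates (stage, age, sex, race, histology, smoking, TMB,
MSI score, prior treatment, metastasis — whichever are present).
Weights are stabilized (marginal prevalence over propensity), keeping
the mean weight near 1. Balance is reported as standardized mean
differences, factors expanded to indicators, before and after
weighting. Positivity is enforced where it matters for the weights: the
fit errors when a treated patient's propensity is within 1e-6 of 0,
a reference patient's within 1e-6 of 1, or both extremes occur at once
(complete separation). Near-zero propensities among reference patients
alone leave their stabilized weights near 1 and are tolerated — with
rare covariate levels and small arms they are sampling noise, not an
overlap violation. An optional 1st/99th-percentile propensity
truncation (off by default) is used inside bootstrap refits, where
resampled small arms routinely produce such levels.

**Weighted, left-truncated Cox.** Time zero is diagnosis; a patient
enters the risk set only at sequencing, which removes the
immortal-time bias of conditioning on surviving to be sequenced. Fits
use `survival::coxph` with case weights and the robust sandwich
variance, since IPTW invalidates the information-based variance. The
test suite pins the implementation to a hand-coded delayed-entry
partial likelihood on a six-patient fixture and to the classical fit
when weights are unit and entry is at diagnosis.

**The RR metric.** RR is a ratio of two hazard ratios sharing the
no-mutation reference arm. Its CI comes from a patient-level
nonparametric bootstrap that re-runs both weighted fits per resample
(percentile interval); replicates whose arms empty are dropped and
counted, and more than 20% drops aborts. A bootstrap was chosen over a
delta-method interval because the two fitted HRs share patients and
weights, and no variance formula for that dependence is assumed.

**Weighted KM.** The product-limit estimator with weighted risk/event
counts and delayed entry, via `survival::survfit`; strata under 10
patients are dropped with a warning, per the strata-size rule used for
reporting curves.

**Strata precedence.** A patient carrying both a known oncogenic
mutation and a reclassified VUS in the gene is assigned to the
oncogenic stratum: precedence follows strength of evidence
(oncogenic > reclassified pathogenic > reclassified benign >
no mutation). Carriers of only uncertain- or missing-class VUSs fall
in no-mutation by default, with an option to exclude them instead.

**Mutual exclusivity tables.** The one-vs-all table rows split patients
by carrying a reclassified-pathogenic mutation in the focal gene; the
columns split by carrying a known oncogenic mutation in *any* pathway
gene, the focal gene included. Patients with an oncogenic focal-gene
mutation but no reclassified one therefore land in the "VUSs/no
mutation" row while still counting in the oncogenic column — the
documented construction is followed literally. `OR_mutex`, by contrast,
excludes the focal gene from its column ("*other* oncogenic
mutations"); the two definitions intentionally differ. The BH family is
all (gene, pathway, method) tests in one invocation. Per-gene panel
filtering is applied to the mutex cohort, matching the survival
benchmark's rule; this is an assumption where the filtering scope was
not fully specified.

**Ensemble.** Z-scores use the sample (n−1) standard deviation, fitted
on training rows only. Instances with any missing method score are
dropped before the split, mirroring the choice of maximally annotated
variants for the negative class; median imputation is available behind
a flag. Gene-holdout folds partition genes, so no gene spans training
and validation; with population-level instances, duplicate occurrences
of a variant stay on one side of the split to avoid leakage (stricter
than strictly required, recorded as a deviation). mtry is tuned over
{1, 2, 3, ⌊√p⌋} by CV AUROC; forests default to 500 trees.

## The synthetic cohort generator

Real cohorts of this kind (multi-institution tumor registries with
linked survival) are access-gated, so every benchmark is exercised
against a generator whose latent truth is recorded:

* **Genes** carry an NSCLC-like default panel (KEAP1, STK11, SMARCA4,
  EGFR, KRAS, NFE2L2, CUL3, NF1, ERBB4, IRS2, TP53, ATM) with
  per-patient mutation probabilities, a known-oncogenic fraction, a
  latent-driver fraction among VUSs, and true log hazard ratios per
  carrier class. KEAP1 pathogenic mutations carry the reference true
  hazard ratio of 2.0. Oncogenic and VUS mutations are drawn
  *independently within a gene*, so no structural within-gene
  exclusivity is baked in.
* **Scores** are class-conditional Beta draws on [0, 1] per method —
  bounded scores resemble most VEP outputs — with negative orientation
  implemented by reflection, so one sampler serves both. The analytic
  AUROC of the two Betas is computable by quadrature (`beta_auroc`) and
  the suite checks the empirical separation against it.
* **Binding residues** are arranged by solving exactly (up to integer
  rounding) for the split of binding sites between driver and passenger
  residues that achieves the configured driver-vs-passenger odds ratio
  (default 5).
* **Mutual exclusivity** is induced by rejection sampling: a patient's
  mutation configuration is accepted with probability
  OR^(C(d, 2)) where d counts driver mutations in the pathway (each
  oncogenic mutation and each latent-driver VUS is a unit, so
  within-gene redundancy is thinned like cross-gene redundancy). Under
  independence this yields a pairwise co-occurrence odds ratio equal to
  the target; OR = 1 leaves draws untouched, which is how the
  type-I-error calibration of the mutex battery is tested.
* **Survival** is exponential proportional hazards: per-patient log
  hazard is the sum of gene-class effects plus a smoking effect, entry
  is uniform within 12 months of diagnosis, censoring is administrative
  at 60 months, and only patients alive at entry are observed —
  accept/reject sampling of that condition keeps exactly `n_patients`
  while reproducing genuine left truncation. Smoking also shifts
  mutation odds, so it genuinely confounds naive gene–survival
  associations.
* **Contexts** come from a smoking-exposed-lung-like SBS96 profile
  (C>A dominant, C>T secondary), and each variant is represented on a
  random strand so reverse-complement handling is exercised.

Two purpose-built configurations freeze the recovery studies:
`recovery_config` (one gene, true HR 2.0, smoking shifting mutation
odds by +1.5 log odds and hazard by +1.0 log hazard) for IPTW bias
correction, and `rr_config` (driver and passenger VUSs in one gene, no
confounding, true RR 2.0) for bootstrap-CI coverage. The confounder in
`recovery_config` is strong because marginal hazard ratios are
non-collapsible: part of any confounder's raw imbalance is absorbed
when marginalizing, and the study condition requires the naive estimate
to be visibly biased (by more than 0.15 on the log scale) while IPTW
recovers the truth.

What the generator does **not** emulate: copy-number and structural
variants, clonal hematopoiesis artifacts, panel-specific base-pair
footprints, informative censoring, correlated scores across methods
(scores are conditionally independent given the latent class), and
score-difficulty gradients within a class. Passing tests therefore show
the machinery is correct under the stated model, not that any
particular VEP is good on real data.

## Problem sizes

The test suite and acceptance script use sizes chosen to make each
statistical check decisive at desk scale: 2 000-patient cohorts for
survival recovery (100 replicates), 1 000-patient cohorts for mutex
calibration (~200 gene-pathway pairs) and power (~100), 100-seed
bootstrap coverage runs at n = 800 with 200 resamples, 10^5 draws for
simulator fidelity (total-variation tolerance 0.02), exhaustive
enumeration of all 2×2 tables with N ≤ 12, and 1 000 random instances
for the AUROC and cutpoint oracles.

## Known limitations

* The DeLong variance on upsampled (duplicated) negatives understates
  the correlation induced by duplication; the module mirrors the
  published procedure but a grouped-jackknife diagnostic over unique
  negatives is the honest companion when negatives are few.
* `OR_mutex` is underpowered at the gene level for rare carriers; the
  result is flagged rather than forced.
* The propensity model is main-effects only; interactions or splines
  are deliberately out of scope and the model form is documented as an
  assumption, not asserted as the original studies' choice.
* Multi-sample patients contribute mutations as the union over samples;
  the earliest sequencing defines cohort entry.

## A worked run

```{r example, eval = FALSE}
cohort <- generate_cohort(sim_config(n_patients = 2000, seed = 1))
res <- run_pipeline(cohort, out_dir = "results", seed = 1)
res$roc                      # per-method population-level AUROC + CI
res$binding$deep_struct      # OR_binding
res$survival$deep_struct$rr  # RR for KEAP1
res$mutex_rates              # per-pathway mutual exclusivity rates
```

`scripts/acceptance.R --seed 1 --out results/acceptance.json`
re-derives the headline quantities of this run from scratch.
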