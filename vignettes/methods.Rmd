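---
title: "Methods: validating EHR-derived phenotypes with synthetic genetic data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: validating EHR-derived phenotypes with synthetic genetic data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Overview

`ehrgenval` implements a genetic-validation workflow for phenotypes derived
from electronic health records: rule-based and classifier-based
case-control definition, genotype quality control, SNP-based heritability
and genetic correlation by LD score regression with liability-scale
conversion, and genome-wide heterogeneity testing. Because the registries
and genotypes such studies rest on are not redistributable, the package
pairs every analysis component with a synthetic generator whose truth is
known, and the test suite validates the components against that truth.
This vignette records the models, the tunable parameters, the numerical
choices, and the places where a design decision was genuinely open.

# The phenotyping model

## Latent truth and record generation

Each synthetic patient carries a hidden diagnosis in
`{BD, OTHER_PSYCH, NONE}` drawn with probabilities
(`prevalence_bd` = 0.01, `p_other_psych` = 0.10, remainder). The 1%
bipolar prevalence is the standard population figure for the disorder and
is also the prevalence used in the liability conversion, so the generator
and the estimator agree by construction. Encounters are drawn per patient
(`mean_encounters` = 8, Poisson plus one), with inpatient stays spanning up
to 14 days and outpatient visits a single day. Coded diagnoses follow the
latent label: bipolar patients emit ICD-9 codes from the manic/bipolar
ranges 296.0\*–296.1\* and 296.4\*–296.8\* with per-encounter miscoding
probability `coding_noise` (default 0.10); other-psychiatric patients emit
depression, schizophrenia and anxiety codes, with the reverse miscoding at
the same rate. The ranges 296.2\*/296.3\* (major depression) are present as
confusers and never count as bipolar codes; matching is by string prefix on
the first digit after "296.", mirroring the wildcard notation of the coded
ranges.

Two chronic-ambiguity subtypes among the other-psychiatric group scale with
`coding_noise` and are what give the algorithms realistic positive
predictive values rather than PPV = 1:

- a *BD-like* subtype (frequency `0.25 × coding_noise`) whose record
  resembles a bipolar patient's — mostly bipolar codes, mood-stabilizer and
  antipsychotic orders, specialty-clinic visits. These pollute all coded
  algorithms and the note-feature classifier.
- a *single-visit mimic* (frequency `0.7 × coding_noise`) with one
  inpatient rule-out episode carrying two bipolar codes plus valproate and
  an atypical antipsychotic, and no psychiatric follow-up. These satisfy
  only the single-visit relaxation, which is why that algorithm's PPV sits
  near one half while the stricter algorithms stay near 0.8 — the
  qualitative pattern the validation design is built to expose. The
  frequencies were fixed once, by construction of the mechanism, so that
  the single-visit PPV falls in the neighbourhood of 0.5 at default noise;
  they are configuration, not estimates of any real system.

As `coding_noise` tends to 0 and `med_adherence` to 1 every error mechanism
vanishes and the strict algorithm's PPV tends to 1; the test suite asserts
PPV at least 0.95 at noise 0.01. A `sparse_bd_prob` fraction (0.15) of true
bipolar patients have single-episode records, so the single-visit
relaxation also captures genuine cases — without them its PPV would be
purely a false-positive rate rather than a mixture.

Note features are class-conditional Gaussian surrogates for NLP-extracted
counts: `n_informative` = 10 of `n_note_features` = 50 features shift by
`feature_effect_size` = 0.66 for bipolar patients (0.3 and 0.15 of that for
the BD-like and mimic subtypes). The implied single-index separation is
about 2.1 standard deviations, i.e. an oracle AUC near 0.93, chosen to
match the operating regime in which such classifiers are reported to work
(high specificity, moderate sensitivity). Real note features are counts,
correlated and heavy-tailed; none of that is emulated, so classifier
results here demonstrate the training and thresholding machinery, not
expected real-data performance.

## The five algorithms

The coded rules are pure functions of the record (the suite asserts
invariance to row permutations):

- **coded-strict**: at least three bipolar codes on three distinct dates
  (same-day duplicates collapse; configurable), a predominance of bipolar
  codes, and either a lithium/valproate order within `med_window_days`
  (365) *after* the first bipolar code or any bipolar-specialty encounter.
- **coded-broad**: at least two bipolar codes on distinct encounters,
  predominance, and orders from at least two of
  {lithium, valproate, carbamazepine, atypical antipsychotic}.
- **coded-broad-SV**: identical but the two codes may share one episode.
- **control**: age ≥ 30 with no code in the psychiatric (290–319) or
  neurological (320–359) ICD-9 ranges and no order from a psychotropic
  medication class. Controls come from the full population, not the
  datamart.
- **95-NLP**: a two-stage adaptive LASSO over note features — stage 1
  unpenalized (or ridge when features are many) logistic fit for initial
  coefficients, stage 2 L1 fit with penalty weights 1/|b̂|^γ, γ = 1,
  penalty strength by 5-fold cross-validated deviance — thresholded at the
  smallest cutoff reaching specificity 0.95 on a held-out split.

Open definitions resolved here, exposed in `rule_config()`: "predominance"
is bipolar codes strictly exceeding half of all psychiatric codes (the
denominator excludes non-psychiatric codes); "within a year" anchors at the
earliest bipolar code and looks forward (treatment follows diagnosis);
an "episode" is one encounter for inpatient stays and one calendar date
for outpatient care. Assignment is non-hierarchical: a patient receives
every label whose rule fires. Case and control labels cannot collide
because controls require zero psychiatric codes while every case rule
requires bipolar codes; the assignment function asserts this.

# The genetic model

## Genotypes and liabilities

Genotypes are generated in LD blocks: within a block of `ld_block_size`
SNPs (default 20–25), each haplotype is a thresholded exchangeable Gaussian
copula with latent correlation `within_block_r` (0.5); two independent
haplotypes sum to the dosage, so every SNP is in Hardy-Weinberg proportions
at its MAF (drawn uniform on [0.05, 0.5]) by construction. Block LD with a
known exchangeable structure was chosen over realistic LD decay because it
gives analytically predictable LD scores for oracle tests; LD scores used
in estimation are always computed empirically, with the small-sample
adjustment r̃² = r² − (1−r²)/(n−2) and a window measured in SNPs (default
twice the block size).

Effects are infinitesimal: per SNP, a bivariate normal pair with variance
`h2_liability/M` per trait on the standardized-genotype scale and
correlation `rg_true` across traits (defaults 0.23 and 0.83, matching the
scale of consortium estimates for the disorder). Liability is the genetic
value plus N(0, 1−h²) noise; a case exceeds Φ⁻¹(1−K).

## Two sampling modes

Ascertaining cases at K = 0.01 exactly requires simulating roughly
100 individuals per case. `simulate_panel()` therefore offers:

- **population** mode — exact: draw unascertained individuals in chunks,
  keep cases and controls until quotas are met. Used for small-scale unit
  tests (Hardy-Weinberg checks, threshold semantics, relatedness
  fixtures).
- **retrospective** mode (default) — draw genotypes *conditional* on
  case/control status through the small-effect approximation: SNP j's
  conditional allele frequency is shifted by Cov(xⱼ, L)·i/2 per haplotype,
  with selection intensity i = φ(t)/K for cases and −φ(t)/(1−K) for
  controls, and Cov(xⱼ, L) aggregating the LD-weighted effects of the
  block via a three-term tetrachoric (Mehler) expansion of the latent
  copula. The aggregation matters: shifting each SNP by its own effect
  alone produces association signal that is flat in the LD score and lands
  in the regression intercept rather than the slope. With aggregation the
  marginal structure E[χ²ⱼ] = 1 + N h² ℓⱼ/M is reproduced and block LD is
  preserved. The approximation is first-order in the effect sizes, so at
  strong ascertainment it recovers heritability with a modest upward bias
  relative to the configured truth; the package relies on it for ordering
  and structure (misclassification attenuation, pipeline substrate), while
  calibration-grade recovery tests use `simulate_sumstats()`, which draws
  z-scores from the LD score regression model itself and is exact.

Case misclassification is a label swap at sampling time: a
`misclassification_rate` fraction of labelled cases is drawn from the
non-case distribution, the generative analogue of a phenotyping algorithm
with PPV = 1 − rate. Swapping labels rather than corrupting genotypes
matches the diagnostic interpretation: the genome is right, the chart is
wrong.

# Quality control

`qc_pipeline()` applies, per genotyping batch and in order: SNP
missingness > 0.05; sample missingness > 0.02 and heterozygosity deviation
|F| > 0.2; then SNP missingness > 0.02, case-control differential
missingness > 0.02, and Hardy-Weinberg exact-test failures (p < 1e−6 in
controls, p < 1e−10 in cases); after merging, cross-batch differential
missingness > 0.005 and control-vs-control allelic batch association
p < 5e−8. A SNP failing in any batch is removed globally — only SNPs clean
in every batch survive the merge. Counts conserve at every step and an
emptied panel is an error naming the step.

Numerical and definitional choices:

- The HWE test is the exact conditional test (sum of heterozygote
  configurations with probability ≤ observed), computed in log-factorials;
  at thresholds like 1e−10 a chi-square approximation would be unusable.
  The suite checks exact agreement with a full-enumeration oracle for all
  tables with 2n ≤ 60.
- "Heterozygosity deviation" is the method-of-moments statistic
  F = (E[het] − observed het)/E[het] with expectations from panel allele
  frequencies; the underlying metric is a convention, not a claim, and the
  threshold is configurable. Its sampling noise scales like
  1/√(SNPs × mean 2pq) inflated by LD, so the 0.2 threshold is meaningful
  only for panels of a few thousand SNPs or more; threshold-based QC on
  small noisy panels is *not* idempotent in general, and the idempotence
  property is asserted at study-like scale.
- The sex check is skipped with a message when the panel has no
  X-chromosome SNPs, which synthetic defaults do not.
- PCA ancestry selection computes unit-norm eigenvectors of the
  standardized sample-relationship matrix (the PLINK/EIGENSTRAT coordinate
  convention) on study plus reference samples and keeps study samples
  whose (PC1, PC2) distance to the target-population centroid is strictly
  below 0.01. The absolute threshold only has meaning relative to this
  coordinate convention, and both leading PCs must be ancestry-informative
  for within-cluster spread to fall below it — which is why the reference
  fixture carries three populations, as continental reference panels do.
- Relatedness uses PLINK-style method-of-moments IBD (P(IBD = 0, 1, 2)
  from IBS counts and allele frequencies, π̂ = P1/2 + P2), without
  finite-sample frequency corrections — adequate at the package's scales,
  where duplicate (π̂ ≈ 1) and parent-offspring (π̂ ≈ 0.5) pairs are
  separated from unrelated pairs by wide margins. Pruning is greedy by
  descending π̂, removing the pair member with higher missingness, ties
  broken toward the lexicographically later id.

# Association and LD score regression

`run_gwas()` fits per-SNP logistic regressions of status on dosage with
optional PC covariates. The Wald test (per-SNP `glm`) is the default, with
a fully vectorized Rao score test (`method = "score"`) against the
covariate-only null for genome scale: score-based `beta = U/V`,
`se = 1/√V`, identical z to first order. Missing dosages are mean-imputed
per SNP; separated fits are flagged and excluded downstream. The `N`
column stores the total sample size by default, with the effective-size
convention 4/(1/Ncase + 1/Nctrl) available and recorded in the file
header, since downstream LDSC consumers must know which is in use.

`ldsc_h2()` regresses χ² on ℓ with two-step heteroskedasticity weights
1/(2 max(ℓ,1)(1 + N h²₀ ℓ/M)²), h²₀ from the first pass (clamped to
[0, 1]); the intercept is free, absorbing confounding. Standard errors are
a delete-a-block jackknife over contiguous SNP blocks (200 by default,
reduced to M/50 for small panels, minimum 2); significance is the
one-sided normal test of h² > 0, invariant to the liability conversion
because estimate and SE scale together. SNPs with χ² above
max(80, 0.001 N) are dropped before fitting (configurable; disabled for
noiseless closed-form tests, which must invert the model exactly).
`ldsc_rg()` uses the same two-step weighting on z₁z₂ with the cross-trait
covariance in the weights, so identical inputs give exactly r_g = 1; the
cross-trait intercept is free (sample overlap), the SE jackknifes the full
ratio (per-trait slopes re-estimated per block, with a rescaled-covariance
fallback when leave-one-out heritabilities go non-positive), and a
non-positive heritability on either side makes the correlation undefined,
returned as missing with an explanatory reason rather than a number.
Estimates beyond |r_g| = 1.25 trigger a warning as noise-dominated.

`cochran_q()` is the standard fixed-effect heterogeneity statistic on
betas and SEs (a z-based variant would differ only by the allele-frequency
scaling of the betas); `q_scan()` selects SNPs strictly below p = 0.001 in
the *reference* study only — selecting on the compared cohorts would
induce heterogeneity through winner's curse — aligns alleles by sign
flips, and Bonferroni-corrects over the SNPs actually tested after
alignment.

# The end-to-end pipeline

`run_pipeline()` composes the stages: EHR generation; phenotyping with the
classifier trained on a 400-patient chart-review-labelled subset of the
datamart; genotype simulation *conditioned on each genotyped individual's
latent diagnosis* — labelled cases whose latent truth is not bipolar
receive non-case genotypes, which is the mechanism by which phenotyping
error becomes heritability attenuation; QC; per-cohort GWAS (cohorts per
algorithm, the union of all, and the union excluding the single-visit
algorithm, each against shared controls); LDSC per cohort with the cohort's
realized case fraction; genetic correlation of each cohort against an
independently sampled reference-consortium cohort built on the same
genetic architecture with the trait-2 effects (correlation `rg_true`); the
pairwise cohort r_g matrix; and a Q scan of the combined cohort against
the reference. Every stage artifact is a plain-text file under the output
directory, all randomness derives from the single seed, and the report is
byte-reproducible.

Default scales — 20,000 patients, 5,000 SNPs, 1,500 controls, a
2,500 + 2,500 reference cohort — were chosen so a full run completes in
well under a minute on one CPU while keeping at least 100 SNPs per
jackknife block. At 1% prevalence those scales yield a few hundred cases
per cohort, so per-cohort heritability and correlation estimates carry
standard errors of order 0.2 and individual runs are noise-dominated; the
report flags any estimate more than 3 SE from the configured truth, and
the recovery-grade evidence for the estimators comes from the
`simulate_sumstats()` tests at M = 20,000, N = 50,000, where the suite
requires the mean of 50 seeded estimates inside [0.21, 0.25] for
h² = 0.23, 2-SE coverage of at least 90%, and mean r̂_g inside
[0.78, 0.88] for r_g = 0.83.

# What passing tests do and do not show

The generators emulate the *statistical structure* of the real design:
longitudinal coded records with calibrated diagnostic error, liability-
threshold genetics with known h²/r_g/prevalence, batch structure,
ascertainment and misclassification. They do not emulate real ICD coding
practice, medication dosing or duration, free-text notes, LD decay,
imputation error, population admixture beyond discrete clusters, or
relatedness structure beyond planted pairs. Passing tests therefore
demonstrate that the algorithms and estimators are implemented correctly
and behave as theory predicts under a known truth — not that any
particular real EHR system would achieve these PPVs or heritabilities.
Real-data values from the validation literature enter only as worked
examples of the liability conversion arithmetic and as the scale at which
generator parameters were fixed.

Known limitations, beyond the emulation gaps above: the retrospective
conditional draw is first-order and slightly optimistic on h² at strong
ascertainment; threshold-based QC is idempotent only when sample statistics
sit well inside the thresholds; the adaptive-LASSO threshold is calibrated
on a single held-out split, so its realized specificity on fresh data
fluctuates with binomial noise; and pairwise r_g between cohorts sharing
controls is inflated by correlated sampling noise, exactly as it is in
real non-hierarchical designs — the free cross-trait intercept absorbs
most but not all of it at small N.
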