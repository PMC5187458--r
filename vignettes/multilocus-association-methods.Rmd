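---
title: "Methods: multi-locus penetrance and association analysis for canine DCM/AF"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-locus penetrance and association analysis for canine DCM/AF}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wolfhoundDCM)
```

This vignette documents the statistical methods, modelling assumptions,
parameter conventions and numerical choices behind `wolfhoundDCM`. The
package implements a complete case-control association workflow for
dilated cardiomyopathy (DCM) and atrial fibrillation (AF) in Irish
Wolfhounds genotyped at a small panel of biallelic SNPs, together with a
synthetic-cohort simulator that makes every stage testable without raw
study data.

## 1. Phenotype classification

Dogs enter the analysis from longitudinal heart-screening records
(auscultation/ECG/echo visits, each flagged for DCM and AF). A dog ever
diagnosed with DCM **or** AF is *affected*, regardless of age. A
never-diagnosed dog is *unaffected* only if it had a clean heart test
after a sex-specific minimum age; every other dog is *excluded* with
exactly one reason (`unknown_age`, `died_before_threshold`,
`under_threshold`, `not_tested_since_threshold`, applied in that order of
precedence).

The default minimum ages — 6.5 years for males, 8.5 years for females —
are the ages by which 80% of ultimately affected dogs of each sex had
been diagnosed, computed by `onset_quantile_threshold()` from onset ages
binned in half-year bins (smallest bin upper edge whose cumulative
fraction reaches the policy quantile). Both the quantile (default 0.8)
and the bin width (0.5 y) are fields of `grouping_policy()`, so a
stricter 90% policy is a parameter change, not a code change.

`summarize_af_dcm()` quantifies the AF-before-DCM relationship: for dogs
with both diagnoses, the lag from first AF to first DCM diagnosis (a DCM
diagnosis at or before the first AF counts as simultaneous, lag 0); for
AF-only dogs, the time from first AF diagnosis to the last heart test. A
two-sample t-test (pooled-variance by default, Welch behind a flag)
compares the two duration samples. Sex comparisons use a pooled t-test on
onset age (`sex_onset_comparison()`, with a sensitivity variant dropping
dogs first diagnosed late at their very first test, whose true onset age
is uncertain) and an uncorrected Pearson chi-square on the 2×2
affected-by-sex table (`sex_proportion_test()`).

## 2. Penetrance models

For one biallelic locus with genotype classes ordered by copies of the
risk allele (a/a, A/a, A/A), the four penetrance models are:

| model          | f(a/a) | f(A/a)      | f(A/A)           |
|----------------|--------|-------------|------------------|
| multiplicative | f0     | f0·γ        | f0·γ²            |
| additive       | f0     | f0·γ        | 2·f0·γ           |
| recessive      | f0     | f0          | f0·γ             |
| dominant       | f0     | f0·γ        | f0·γ             |

with every component capped at 1 (`penetrance_vector()`). Orientation is
fixed before fitting: a/a is the homozygote with the lower observed risk
(ties broken alphabetically), so γ ≥ 1 corresponds to the risk allele.

`fit_penetrance()` estimates (f0, γ) by minimising the Pearson
goodness-of-fit chi-square between observed affected counts and
penetrance-times-total expected counts. The published analyses this
reproduces do not print an estimator, so the package's is a documented
choice: a vectorised coarse grid over f0 ∈ (0, 1] (step 0.01) × γ ∈
[0.1, 10] (step 0.05), followed by L-BFGS-B refinement from the best grid
point with box constraints f0 ∈ [1e-4, 1], γ ∈ [0.1, 10]. The surface is
smooth and two-dimensional, so this is deterministic, takes ~40 ms per
model, recovers χ² < 1e-6 on tables lying exactly on a model surface, and
matches an exhaustive fine-grid search on the packaged tables (tested).

`select_penetrance_model()` fits all four and keeps the smallest
minimised χ², with ties broken in the fixed order multiplicative,
additive, dominant, recessive. The winner routes the locus to its
association test: multiplicative → allelic, additive → Cochran-Armitage
trend (scores 0, 1, 2), dominant → pooled-dominant, recessive →
pooled-recessive. Model selection is *descriptive* (smallest χ², no
penalty for the equal parameter counts); on simulated tables of a few
thousand individuals the generating kind is recovered in ≈99/100 seeds.

A caveat tested explicitly: case-control sampling at an artificial
case fraction distorts the *scale* of penetrances (they are only
identified up to the sampling odds), but preserves the dominant/recessive
*shape*. Recovering γ itself requires prevalence-proportional sampling;
the acceptance suite does this with case counts matching the population
prevalence implied by the generating model.

## 3. Association statistics

### 3.1 Expected counts from unaffected proportions

The workflow's native statistic compares observed affected counts per
category (genotype, allele, pooled class, or multi-locus combination)
against expectations derived from the *unaffected* group:
E_i = (u_i / Σu) · Σa (`expected_affected()`), followed by the
goodness-of-fit sum χ² = Σ (O_i − E_i)²/E_i over affected categories
(`chisq_gof()`). Degrees of freedom are k − 1 over all k categories.
Categories with zero expected count contribute nothing to the sum but
**keep their place in the degrees of freedom** — this zero-expected-cell
rule is load-bearing: the packaged three-locus combination table has one
class with no unaffected dogs, and only this convention reproduces its
published χ² = 41.09 with df 7 and p = 7.8e-7.

The allelic test doubles genotype counts into allele space (each
individual contributes two observations); the pooled tests first merge
the heterozygote with the like-penetrance homozygote; the trend test is
the standard Cochran-Armitage statistic (hand-written; equal to
`stats::prop.trend.test` with scores 0, 1, 2, which is tested).
Bonferroni correction is `min(1, p × family)`; the single-locus panel
uses family 5, the pairs stage family 3.

### 3.2 Calibration: a measured warning

The unaffected-proportion construction treats the unaffected sample as
*fixed*, ignoring its own sampling noise. Measured under the null (γ = 1,
Hardy-Weinberg genotypes), it rejects at ≈18% nominal-5% with 500/500
cases/controls and ≈33% at the study-like 72/23 imbalance — it is
markedly anti-conservative, and increasingly so as the unaffected group
shrinks. It is nevertheless the package default because reproducing the
printed statistics is the package's purpose.

For calibrated inference, `run_association(..., contingency = TRUE)`
computes the standard full k×2 Pearson contingency statistic (identical
to `chisq.test(correct = FALSE)`, which is tested), whose measured
rejection rate is 5% ± 1.5% over thousands of null replicates. The test
suite asserts *both* behaviours: calibration of the contingency variant
and anti-conservativeness of the default. Treat the default's raw
p-values as reproduction artefacts, not as calibrated error rates.

## 4. Relative risk against the whole population

`relative_risk()` divides a genotype class's risk (affected/total) by the
**whole classified population's** risk, and builds a log-method CI

    exp( ln rr ∓ z · sqrt(1/a − 1/n + 1/A − 1/N) ),  z = qnorm(0.975)

treating the genotype subset and the population as independent samples,
even though the population contains the subset. This is non-standard but
is exactly the construction that reproduces every published 2-dp CI from
reconstructed counts (an 87-value regression test); the standard
disjoint-complement comparison is available via
`reference = "complement"`. Classes with zero affected get rr = 0 with an
undefined, flagged CI — no printed convention exists for them. A row is
flagged `significant` when its CI excludes 1.

## 5. Pooling and multi-locus combinations

`pool_genotypes()` merges single-locus classes before risk estimation:
under a dominant model the heterozygote joins the at-risk homozygote,
under a recessive model the least-risky homozygote; `small_count` merges
any genotype with fewer than 5 carriers (configurable) into the
heterozygote class. Pooled labels are heterozygote-first (`"GA/GG"`,
`"CT/TT"`), counts are conserved exactly, and the genotype-to-class
mapping is attached as an attribute so cohort-level cross-tabulation can
reuse it. `cross_tabulate()` builds combination tables over 2–3 loci,
dropping dogs missing a call at any involved locus;
`multilocus_association()` and `multilocus_risks()` then apply the
statistics above per combination class.

## 6. PCR-RFLP genotype calling

Each locus definition carries amplicon length, restriction enzyme,
cut-allele and digest fragment sizes. `call_genotype_from_bands()` calls
genotypes from observed gel bands: full-length band only → uncut
homozygote; digest fragments only → cut homozygote; both → heterozygote.
Band sizes match within ±10 bp (roughly 2% agarose resolution in the
100-400 bp range); fragments under 40 bp are optional (they routinely run
off the gel) while larger fragments are mandatory; any unexplained band
or missing mandatory fragment is a no-call with a diagnostic, never a
guess. `validate_loci()` checks each definition's fragments sum to its
amplicon length — in the packaged panel exactly one primer set (the Chr21
new-forward set) fails, by 13 bp, as published; the discrepancy is
reported, not corrected.

## 7. The synthetic-cohort simulator

`simulate_cohort()` generates per-dog records under explicit, seeded
assumptions:

- **Genotypes**: independent loci, Hardy-Weinberg, risk-allele copies ~
  Binomial(2, allele frequency).
- **Disease liability**: per-locus penetrances from the model table
  above, combined across loci as `independent_or`
  (1 − Π(1 − p_l); independent causes) or `product_capped`.
- **Onset**: truncated-normal age at DCM onset, sex-specific means
  (defaults 4.82 y male, 6.14 y female) with sd 2.0 y; AF accompanies DCM
  simultaneously with probability 0.586, otherwise precedes it by
  Uniform(0, 3] years.
- **Observation**: heart tests on a fixed schedule (1.5 y, then yearly to
  12 y); diagnoses are seen at the first test at/after onset; competing
  non-cardiac mortality is exponential (rate 0.1/y); genotypes drop out
  at 8%.

The default five-locus panel mirrors the study's allele frequencies and
model kinds, with per-locus f0 = 0.25 chosen so the classified-population
lifetime risk lands near the observed 0.76. These defaults are study
conditions, not tuning knobs. `simulate_count_table()` skips the cohort
machinery and draws case/control genotype counts directly from the Bayes
inversion P(g | case) ∝ HWE(g)·pen(g) — the right tool for statistical
calibration experiments.

The simulator is a *test harness*, not an epidemiological model: no
linkage disequilibrium, no polygenic background, no age-dependent
penetrance, no family structure, and screening attendance independent of
health status.

## 8. Numerical choices and problem sizes

- Chi-square tails via `stats::pchisq`; t-tests via `stats::t.test`; the
  2×2 sex test via `stats::chisq.test(correct = FALSE)`; z = `qnorm(0.975)`
  = 1.959964 rather than a rounded 1.96 (both reproduce the printed 2-dp
  CIs).
- Fixture counts are reconstructed as `round(risk × total)` from printed
  (risk, total) pairs; the reconstruction is verified self-consistent
  (`round(affected/total, 2)` returns the printed risk) for every row.
- Typical costs on one CPU: full four-model selection ~0.2 s per locus; a
  20,000-dog cohort simulation ~4 s; the entire test suite ~25 s. The
  calibration experiments in the acceptance suite use 500-2,000 seeded
  replicates, sized so Monte-Carlo error is well inside the asserted
  tolerances.

## 9. Known limitations

- The default association statistic is anti-conservative (see §3.2); use
  `contingency = TRUE` when calibration matters.
- Penetrance scale (f0, γ) is not identified from artificially balanced
  case-control counts, only the model shape is.
- The RR confidence interval inherits the published
  population-as-reference convention; complement-based CIs differ.
- Genotype-table row order follows label sort order, so mixed-case
  simulator labels and uppercase field labels can order differently.
- The simulator's independence assumptions (no LD, independent loci,
  health-independent screening) make it unsuitable for power studies of
  correlated panels.
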