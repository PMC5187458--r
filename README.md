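# wolfhoundDCM

Multi-locus case-control association analysis of dilated cardiomyopathy
(DCM) and atrial fibrillation (AF) in Irish Wolfhounds.

Dilated cardiomyopathy is the leading cardiac disease of the breed:
roughly three quarters of classifiable dogs in long-running screening
programmes are ultimately affected, AF usually appears with or before the
DCM diagnosis, and males are diagnosed years earlier than females. The
genetic signal is not a single Mendelian variant but a handful of common
SNPs whose *combinations* stratify risk: individually each locus moves
lifetime risk only slightly, but carrying the risk genotypes at three
loci together pushes it near certainty.

This package implements that entire analysis as a reproducible pipeline:

- **Cohort I/O** — strict CSV schema for longitudinal heart-screening
  records (`read_cohort()`, `write_cohort()`), with per-row validation
  diagnostics.
- **Phenotype statistics** — affected/unaffected/excluded assignment
  under sex-specific onset-age thresholds derived from the cohort's own
  onset quantiles (`assign_groups()`, `onset_quantile_threshold()`), and
  the AF-DCM lag/duration comparison (`summarize_af_dcm()`).
- **PCR-RFLP typing** — genotype calls from restriction-digest band
  patterns with explicit tolerance and small-fragment rules
  (`call_genotype_from_bands()`, `validate_loci()`).
- **Penetrance fitting** — the core model object: `fit_penetrance()`
  estimates (f0, γ) for the multiplicative, additive, dominant and
  recessive models by chi-square minimisation, returning a classed S3
  fit with `print`, `summary`, `coef`, `predict`, `residuals` and
  `simulate` methods; `select_penetrance_model()` picks the best model
  and routes the locus to its matching test.
- **Association tests** — allelic, Cochran-Armitage trend, pooled
  dominant/recessive, and unpooled genotypic tests with expected counts
  from the unaffected genotype proportions, the zero-expected-cell df
  rule, and Bonferroni family correction (`run_association()`,
  `multilocus_association()`).
- **Risk stratification** — genotype and multi-locus relative risks
  against the whole-population risk with log-method confidence intervals
  (`relative_risk()`, `multilocus_risks()`, `cross_tabulate()`).
- **Simulator** — a seeded Hardy-Weinberg cohort generator with
  truncated-normal sex-specific onset, screening schedules, competing
  mortality and genotype dropout (`simulate_cohort()`,
  `simulate_count_table()`), so every statistical property is testable.
- **Pipeline** — `run_pipeline()` chains all stages from either a cohort
  or pre-tabulated count tables and writes per-stage CSVs plus a text
  report.

## The model

For a biallelic locus with genotypes ordered by risk-allele copies
(a/a, A/a, A/A), disease penetrance is

    multiplicative: (f0, f0·γ, f0·γ²)      additive: (f0, f0·γ, 2·f0·γ)
    recessive:      (f0, f0,   f0·γ)       dominant: (f0, f0·γ, f0·γ)

capped at 1, with a/a defined as the lower-risk homozygote. Association
is tested by a goodness-of-fit chi-square of observed affected counts
against expectations E_i = (u_i/Σu)·Σa taken from the unaffected
genotype proportions; cells with E_i = 0 are skipped in the sum but kept
in df = k − 1. Relative risk of a genotype class is its risk divided by
the whole-population risk, with CI
`exp(ln rr ∓ z·√(1/a − 1/n + 1/A − 1/N))`. Both constructions are
deliberately those of the motivating study — the methods vignette
documents where they differ from textbook practice (the default
chi-square is anti-conservative; a calibrated k×2 contingency variant
sits behind `contingency = TRUE`).

## Worked example

The packaged fixtures reconstruct the published genotype tables from
their printed (risk, total) pairs (classified population: 72 affected of
95). Single-locus analysis at the Chr1 SNP:

```r
library(wolfhoundDCM)
tabs <- iwh_count_tables()
tabs$chr1
#> Genotype count table (Chr1): 61 affected / 19 unaffected
#>   Chr1 affected unaffected
#> 1   CC       44         10
#> 2   CT       15          7
#> 3   TT        2          2

sel <- select_penetrance_model(tabs$chr1)
sel
#> Penetrance model selection (smallest chi-square wins):
#> multiplicative       additive       dominant      recessive
#>         0.0221         1.8519         0.3556         0.1707
#> Winner: multiplicative (risk allele C) -> allelic test

run_association(tabs$chr1, sel$test_type, family_size = 5)
#> allelic association test at Chr1
#>   chi2 = 10.61, df = 1, p = 0.00113 (Bonferroni x5: 0.00563)
#>   highest-risk category: C
```

Combining the three individually significant loci:

```r
multilocus_association(tabs$chr1_chr21_chr37)
#> genotypic association test at Chr1 x Chr21 x Chr37
#>   chi2 = 41.09, df = 7, p = 7.77e-07 (Bonferroni x1: 7.77e-07)
#>   highest-risk category: CC + GA/GG + AA

multilocus_risks(tabs$chr1_chr21_chr37)
#> Risk vs population risk 72/95 = 0.76 (95% CI, log method)
#>                genotype affected total risk   rr ci_low ci_high significant
#> 1       CT/TT + AA + AA        1     2 0.50 0.66   0.16    2.65       FALSE
#> 2    CT/TT + AA + GA/GG        1     4 0.25 0.33   0.06    1.81       FALSE
#> 3    CT/TT + GA/GG + AA        4     5 0.80 1.06   0.67    1.66       FALSE
#> 4 CT/TT + GA/GG + GA/GG       11    15 0.73 0.97   0.70    1.34       FALSE
#> 5          CC + AA + AA        1     2 0.50 0.66   0.16    2.65       FALSE
#> 6       CC + AA + GA/GG        4     4 1.00 1.32   1.18    1.48        TRUE
#> 7       CC + GA/GG + AA       13    14 0.93 1.23   1.02    1.47        TRUE
#> 8    CC + GA/GG + GA/GG       26    34 0.76 1.01   0.81    1.26       FALSE
```

The 14-dog `CC + GA/GG + AA` class shows the headline result: 93%
affected, relative risk 1.23 with a 95% CI that excludes 1.

The same analysis runs end-to-end from the fixtures or from a simulated
cohort with `run_pipeline()`; with `out_dir` set it writes per-stage CSVs
and a text report.

## Documentation

- `vignette("multilocus-association-methods")` — models, assumptions,
  estimator details, calibration measurements and simulator scope.
- Function reference — roxygen documentation on every exported function.
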