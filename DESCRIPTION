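Package: wolfhoundDCM
Title: Multi-Locus Genetic Association Analysis of Canine Dilated
    Cardiomyopathy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Case-control association analysis of dilated cardiomyopathy
    (DCM) and atrial fibrillation (AF) in Irish Wolfhounds genotyped at a
    small panel of biallelic SNPs by PCR-RFLP.  Builds affected/unaffected
    groups from longitudinal heart-screening records using sex-specific
    onset-age thresholds, fits four single-locus penetrance models
    (multiplicative, additive, dominant, recessive) by chi-square
    minimisation, routes each locus to the matching association test
    (allelic, trend, pooled dominant/recessive) with expected counts
    derived from the unaffected genotype proportions, estimates genotype
    relative risks against the whole-population risk with log-method
    confidence intervals, and stratifies risk over two- and three-locus
    genotype combinations.  Includes an in-silico PCR-RFLP genotype caller
    and a Hardy-Weinberg synthetic-cohort simulator so the complete
    pipeline runs and is testable without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, knitr, rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
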