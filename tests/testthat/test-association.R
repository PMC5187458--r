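test_that("expected counts follow the unaffected-proportion construction", {
  e <- expected_affected(c(103, 19), c(27, 11))
  expect_equal(e, c(27, 11) / 38 * 122)
  expect_equal(round(e, 2), c(86.68, 35.32))
  expect_equal(sum(e), 103 + 19)  # conserves the affected total
  expect_error(expected_affected(c(1, 2), c(0, 0)), "unaffected")
  expect_error(expected_affected(c(0, 0), c(1, 2)), "affected")
})

test_that("the goodness-of-fit statistic skips zero-expected cells but keeps df", {
  o <- c(10, 5, 3)
  e <- c(9, 6, 3)
  g <- chisq_gof(o, e)
  expect_equal(g$chi2, brute_chi2(o, e))
  expect_equal(g$df, 2L)
  expect_equal(g$p, pchisq(g$chi2, 2, lower.tail = FALSE))
  gz <- chisq_gof(c(10, 5, 3), c(9, 9, 0))
  expect_equal(gz$chi2, (10 - 9)^2 / 9 + (5 - 9)^2 / 9)
  expect_equal(gz$df, 2L)  # the empty cell still counts toward df
  g1 <- chisq_gof(o, e, df_override = 5)
  expect_equal(g1$df, 5L)
  expect_error(chisq_gof(c(1, 2), c(0, 0)), "zero")
})

test_that("Bonferroni correction is min(1, p * family)", {
  expect_equal(bonferroni(c(0.01, 0.3), 5), c(0.05, 1))
  expect_equal(bonferroni(0.2, 1), 0.2)
  expect_error(bonferroni(0.5, 0))
})

test_that("single-locus tests reproduce the study panel statistics", {
  tabs <- iwh_count_tables()
  a1 <- run_association(tabs$chr1, "allelic", family_size = 5)
  expect_equal(round(a1$chi2, 2), 10.61)
  expect_equal(a1$df, 1L)
  expect_equal(round(a1$p_corrected, 4), 0.0056)
  expect_equal(a1$risk_allele_or_genotype, "C")
  expect_equal(sort(a1$labels), c("C", "T"))
  expect_equal(unname(a1$observed[a1$labels == "C"]), 103)

  a21 <- run_association(tabs$chr21, "pooled_dominant", family_size = 5)
  expect_equal(round(a21$chi2, 2), 7.67)
  expect_equal(a21$df, 1L)
  expect_equal(round(a21$p_corrected, 3), 0.028)
  expect_equal(a21$risk_allele_or_genotype, "GA/GG")

  a37 <- run_association(tabs$chr37, "pooled_recessive", family_size = 5)
  expect_equal(round(a37$chi2, 2), 11.12)
  expect_equal(round(a37$p_corrected, 4), 0.0043)
  expect_equal(a37$risk_allele_or_genotype, "AA")
})

test_that("pair and triple combination tests reproduce the published values", {
  tabs <- iwh_count_tables()
  pairs <- list(chr1_chr21 = c(14.16, 0.0081),
                chr1_chr37 = c(15.56, 0.0042),
                chr21_chr37 = c(24.55, 0.000058))
  for (nm in names(pairs)) {
    a <- multilocus_association(tabs[[nm]], family_size = 3)
    expect_equal(round(a$chi2, 2), pairs[[nm]][1])
    expect_equal(a$df, 3L)
    expect_equal(signif(a$p_corrected, 2), signif(pairs[[nm]][2], 2))
  }

  triple <- multilocus_association(tabs$chr1_chr21_chr37)
  expect_equal(round(triple$chi2, 2), 41.09)
  expect_equal(triple$df, 7L)
  expect_equal(signif(triple$p_raw, 2), 7.8e-07)
  # the zero-expected-cell rule is load-bearing: one combination class has
  # no unaffected dogs yet still counts toward the degrees of freedom
  expect_true(any(triple$expected == 0))
  expect_equal(triple$df, length(triple$observed) - 1L)
})

test_that("the trend test equals the textbook Cochran-Armitage statistic", {
  aff <- c(10, 20, 30)
  una <- c(30, 20, 10)
  ct <- count_table(c("AA", "AG", "GG"), affected = rev(aff),
                    unaffected = rev(una), loci = "ChrX")
  tr <- run_association(ct, "trend")
  expect_equal(tr$chi2, 20)  # worked by hand from the score formula
  # suppress the oracle's internal lm() perfect-fit warning
  pt <- suppressWarnings(stats::prop.trend.test(aff, aff + una, score = 0:2))
  expect_equal(tr$chi2, unname(pt$statistic))
  expect_equal(tr$df, 1L)
  # genotype order follows risk-allele copies: last label is the risk homozygote
  expect_equal(tr$labels, c("GG", "AG", "AA"))
  expect_equal(tr$risk_allele_or_genotype, "AA")
  pooled <- pool_genotypes(ct, pooling_rule("dominant"))
  expect_error(run_association(pooled, "trend"), "unpooled")
})

test_that("genotype-class ordering by risk-allele copies is correct", {
  ord <- order_by_risk_allele(c("CC", "CT", "TT"), c(44, 15, 2), c(10, 7, 2))
  expect_equal(ord, c(3L, 2L, 1L))  # TT, CT, CC: 0, 1, 2 copies of C
})

test_that("the contingency option gives the standard k x 2 Pearson test", {
  tabs <- iwh_count_tables()
  for (nm in c("chr1", "chr37", "chr1_chr21")) {
    a <- run_association(tabs[[nm]], "genotypic", contingency = TRUE)
    ref <- suppressWarnings(
      stats::chisq.test(cbind(tabs[[nm]]$affected, tabs[[nm]]$unaffected),
                        correct = FALSE))
    expect_equal(a$chi2, unname(ref$statistic))
    expect_equal(a$df, unname(ref$parameter))
    expect_equal(a$p_raw, ref$p.value)
  }
})

test_that("the default construction is hotter than the contingency test", {
  # the unaffected-proportion statistic treats the unaffected sample as
  # fixed, so it is systematically larger than the both-margins-random
  # Pearson statistic on the same table
  tabs <- iwh_count_tables()
  for (nm in c("chr1", "chr21", "chr37")) {
    g <- run_association(tabs[[nm]], "genotypic")
    p <- run_association(tabs[[nm]], "genotypic", contingency = TRUE)
    expect_gt(g$chi2, p$chi2)
  }
})

test_that("allele counting doubles each homozygote", {
  ac <- wolfhoundDCM:::allele_counts(c("CC", "CT", "TT"), c(44, 15, 2))
  expect_equal(unname(ac[c("C", "T")]), c(103, 19))
  expect_error(wolfhoundDCM:::allele_counts(c("CT/TT"), 5), "unpooled")
})
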