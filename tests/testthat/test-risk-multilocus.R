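test_that("penetrance-model pooling reproduces the pooled study tables", {
  tabs <- iwh_count_tables()

  same_table <- function(a, b) {
    expect_equal(ct_labels(a), ct_labels(b))
    expect_equal(a$affected, b$affected)
    expect_equal(a$unaffected, b$unaffected)
  }

  p21 <- pool_genotypes(tabs$chr21, pooling_rule("dominant"))
  same_table(p21, tabs$chr21_pooled)
  m21 <- attr(p21, "mapping")
  expect_equal(unname(m21[c("GA", "GG", "AA")]), c("GA/GG", "GA/GG", "AA"))

  p37 <- pool_genotypes(tabs$chr37, pooling_rule("recessive"))
  same_table(p37, tabs$chr37_pooled)
  expect_equal(unname(attr(p37, "mapping")[["GG"]]), "GA/GG")

  # Chr1: TT carried by 4 dogs, below the small-count threshold of 5
  p1 <- pool_genotypes(tabs$chr1, pooling_rule("small_count"))
  same_table(p1, tabs$chr1_pooled)
  expect_true("CT/TT" %in% ct_labels(p1))

  # counts are conserved exactly by every rule
  pooled <- list(chr1 = p1, chr21 = p21, chr37 = p37)
  for (nm in names(pooled)) {
    expect_equal(sum(pooled[[nm]]$affected), sum(tabs[[nm]]$affected))
    expect_equal(sum(pooled[[nm]]$unaffected), sum(tabs[[nm]]$unaffected))
  }

  expect_identical(ct_labels(pool_genotypes(tabs$chr1, pooling_rule("none"))),
                   ct_labels(tabs$chr1))
  expect_error(pool_genotypes(tabs$chr1_chr21, pooling_rule("dominant")))
})

test_that("genotype risk is affected over carrier total", {
  expect_equal(genotype_risk(44, 54), 44 / 54)
  tabs <- iwh_count_tables()
  expect_equal(genotype_risk(tabs$chr1),
               tabs$chr1$affected / (tabs$chr1$affected + tabs$chr1$unaffected))
  expect_error(genotype_risk(3, 0))
})

test_that("relative risk and its log-method CI match the hand formula", {
  r <- relative_risk(44, 54)
  expect_equal(r$risk, 44 / 54)
  expect_equal(r$rr, (44 / 54) / (72 / 95))
  se <- sqrt(1 / 44 - 1 / 54 + 1 / 72 - 1 / 95)
  expect_equal(r$ci_low, exp(log(r$rr) - qnorm(0.975) * se))
  expect_equal(r$ci_high, exp(log(r$rr) + qnorm(0.975) * se))
  expect_equal(round(c(r$rr, r$ci_low, r$ci_high), 2), c(1.08, 0.91, 1.28))
  expect_false(r$significant)

  r2 <- relative_risk(13, 14)
  expect_equal(round(c(r2$rr, r2$ci_low, r2$ci_high), 2), c(1.23, 1.02, 1.47))
  expect_true(r2$significant)

  r0 <- relative_risk(0, 6)
  expect_equal(r0$rr, 0)
  expect_true(is.na(r0$ci_low) && is.na(r0$ci_high) && is.na(r0$significant))

  # the standard disjoint-group comparison remains available
  rc <- relative_risk(44, 54, reference = "complement")
  expect_equal(rc$rr, (44 / 54) / ((72 - 44) / (95 - 54)))
  expect_error(relative_risk(72, 95, reference = "complement"), "empty")

  r90 <- relative_risk(44, 54, conf = 0.90)
  expect_equal(r90$ci_low, exp(log(r$rr) - qnorm(0.95) * se))
})

test_that("every published risk, RR and CI is reproduced at 2 decimals", {
  pub <- iwh_risk_tables()
  rec <- reconstruct_counts(pub$risk, pub$total)
  est <- relative_risk(rec$affected, pub$total)
  expect_equal(round(est$risk, 2), round(pub$risk, 2))
  has <- !is.na(pub$rr)  # RR/CI printed only for headline rows
  expect_gte(sum(has), 29)
  expect_equal(round(est$rr[has], 2), pub$rr[has])
  expect_equal(round(est$ci_low[has], 2), pub$ci_low[has])
  expect_equal(round(est$ci_high[has], 2), pub$ci_high[has])
})

test_that("multilocus risk tables label each combination class", {
  tabs <- iwh_count_tables()
  mr <- multilocus_risks(tabs$chr1_chr21_chr37)
  expect_s3_class(mr, "risk_estimate")
  expect_equal(nrow(mr), 8L)
  expect_equal(mr$genotype, ct_labels(tabs$chr1_chr21_chr37))
  top <- mr[mr$genotype == "CC + AA + GA/GG", ]
  expect_equal(top$total, 4)
  expect_equal(round(c(top$rr, top$ci_low, top$ci_high), 2),
               c(1.32, 1.18, 1.48))
  expect_true(top$significant)
  dcm14 <- mr[mr$genotype == "CC + GA/GG + AA", ]
  expect_equal(round(dcm14$rr, 2), 1.23)
})

test_that("cross-tabulation pools, drops excluded dogs and missing calls", {
  path <- cohort_csv(rows = c(
    "a1,m,no,,alive,3.0:1:0,CC,GA",
    "a2,f,no,,alive,2.0:0:1,CC,GG",
    "a3,m,no,,alive,4.0:1:1,CT,AA",
    "a4,m,no,,alive,3.5:1:0,CC,",     # affected but Chr21 missing
    "u1,m,no,,alive,7.0:0:0,CC,GA",
    "u2,m,no,,alive,8.0:0:0,TT,AA",
    "x1,m,no,,alive,4.0:0:0,CC,GG"))  # excluded: too young
  co <- read_cohort(path)
  asg <- assign_groups(co)
  # mapping keys are canonical genotype labels (alphabetical allele order)
  ct <- cross_tabulate(co, asg, c("Chr1", "Chr21"),
                       mappings = list(Chr21 = c(AA = "AA", AG = "GA/GG",
                                                 GG = "GA/GG")))
  expect_equal(ct_loci(ct), c("Chr1", "Chr21"))
  expect_equal(ct_labels(ct), c("CC + GA/GG", "CT + AA", "TT + AA"))
  expect_equal(ct$affected, c(2L, 1L, 0L))
  expect_equal(ct$unaffected, c(1L, 0L, 1L))
  expect_error(cross_tabulate(co, asg, "Chr1"))
})
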