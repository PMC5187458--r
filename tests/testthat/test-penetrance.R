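test_that("penetrance vectors follow the four closed forms, capped at 1", {
  expect_equal(unname(penetrance_vector("multiplicative", 0.1, 3)),
               c(0.1, 0.3, 0.9))
  expect_equal(unname(penetrance_vector("additive", 0.1, 3)), c(0.1, 0.3, 0.6))
  expect_equal(unname(penetrance_vector("recessive", 0.1, 3)), c(0.1, 0.1, 0.3))
  expect_equal(unname(penetrance_vector("dominant", 0.1, 3)), c(0.1, 0.3, 0.3))
  expect_equal(unname(penetrance_vector("multiplicative", 0.6, 3)),
               c(0.6, 1, 1))  # capped
  expect_equal(unname(penetrance_vector("additive", 0.4, 2)), c(0.4, 0.8, 1))
  expect_error(penetrance_vector("multiplicative", 0, 2))
  expect_error(penetrance_vector("multiplicative", 0.5, -1))
})

test_that("a table lying exactly on a model surface is recovered", {
  tot <- c(AA = 80, AG = 100, GG = 50)
  pen <- penetrance_vector("recessive", 0.2, 2.5)   # 0.2 0.2 0.5
  # orientation: GG is the lower-risk homozygote here
  aff <- c(AA = 0.5 * 80, AG = 0.2 * 100, GG = 0.2 * 50)
  ct <- count_table(names(tot), affected = aff, unaffected = tot - aff,
                    loci = "ChrX")
  fit <- fit_penetrance(ct, "recessive")
  expect_lt(fit$chi2, 1e-6)
  expect_equal(fit$f0, 0.2, tolerance = 1e-3)
  expect_equal(fit$gamma, 2.5, tolerance = 1e-3)
  expect_equal(fit$orientation, c("GG", "AG", "AA"))  # aa, het, AA order
  expect_equal(fit$risk_allele, "A")
  expect_equal(coef(fit), c(f0 = fit$f0, gamma = fit$gamma))
  sel <- select_penetrance_model(ct)
  expect_equal(sel$kind, "recessive")
  expect_equal(sel$test_type, "pooled_recessive")
})

test_that("the optimiser is at least as good as an exhaustive fine grid", {
  tabs <- iwh_count_tables()
  for (nm in c("chr1", "chr21", "chr37")) {
    obs_tot <- tabs[[nm]]
    ori <- wolfhoundDCM:::orient_table(obs_tot)
    obs <- obs_tot$affected[ori$order]
    tot <- (obs_tot$affected + obs_tot$unaffected)[ori$order]
    for (kind in c("multiplicative", "additive", "dominant", "recessive")) {
      fit <- fit_penetrance(obs_tot, kind)
      oracle <- grid_fit_oracle(obs, tot, kind)
      expect_lte(fit$chi2, oracle + 1e-8)
      expect_lt(abs(fit$chi2 - oracle), 0.01)
    }
  }
})

test_that("model selection on the study loci matches the published calls", {
  tabs <- iwh_count_tables()
  s1 <- select_penetrance_model(tabs$chr1)
  expect_equal(s1$kind, "multiplicative")
  expect_equal(s1$test_type, "allelic")
  expect_equal(s1$risk_allele, "C")
  s21 <- select_penetrance_model(tabs$chr21)
  expect_equal(s21$kind, "dominant")
  expect_equal(s21$test_type, "pooled_dominant")
  expect_equal(s21$risk_allele, "G")
  s37 <- select_penetrance_model(tabs$chr37)
  expect_equal(s37$kind, "recessive")
  expect_equal(s37$test_type, "pooled_recessive")
  expect_equal(s37$risk_allele, "A")
  # additive maps to the trend test
  expect_equal(unname(c(multiplicative = "allelic", additive = "trend")["additive"]),
               "trend")
})

test_that("ties break in the order multiplicative, additive, dominant, recessive", {
  # gamma = 1 collapses the multiplicative, dominant and recessive models to
  # the same flat surface, so a table with identical risks in every class
  # fits all three with chi2 ~ 0 (additive cannot be flat: its top class is
  # always doubled); the first model in the tie order wins
  ct <- count_table(c("AA", "AG", "GG"), affected = c(30, 60, 30),
                    unaffected = c(70, 140, 70), loci = "ChrX")
  sel <- select_penetrance_model(ct)
  expect_lt(max(sel$chi2[c("multiplicative", "dominant", "recessive")]), 1e-6)
  expect_gt(sel$chi2[["additive"]], 1)
  expect_equal(sel$kind, "multiplicative")
})

test_that("fit methods: predict, residuals, summary, simulate", {
  fit <- fit_penetrance(iwh_count_tables()$chr37, "recessive")
  p <- predict(fit)
  expect_equal(names(p), fit$orientation)
  expect_equal(unname(p),
               unname(penetrance_vector("recessive", fit$f0, fit$gamma)))
  expect_equal(unname(predict(fit, "GA")), unname(p[2]))  # order-insensitive
  expect_true(is.na(predict(fit, "TT")))

  r_resp <- residuals(fit, type = "response")
  expect_equal(unname(r_resp), fit$observed - fit$expected)
  r_pear <- residuals(fit)
  expect_equal(sum(r_pear^2), fit$chi2, tolerance = 1e-8)

  s <- summary(fit)
  expect_equal(s$table$observed_affected, fit$observed)
  expect_output(print(s), "recessive")

  sims <- simulate(fit, nsim = 3, seed = 5)
  expect_length(sims, 3)
  expect_s3_class(sims[[1]], "count_table")
  expect_equal(sims[[1]]$affected + sims[[1]]$unaffected, fit$totals)
  expect_identical(simulate(fit, nsim = 2, seed = 9),
                   simulate(fit, nsim = 2, seed = 9))
  # empirical mean of simulated affected counts tracks the fitted expectation
  big <- simulate(fit, nsim = 400, seed = 6)
  m <- rowMeans(vapply(big, `[[`, numeric(3), "affected"))
  expect_equal(m, fit$expected, tolerance = 0.1)
})

test_that("degenerate tables are rejected with clear errors", {
  two_het <- count_table(c("AC", "AG", "AA"), affected = c(1, 2, 3),
                         unaffected = c(4, 5, 6), loci = "ChrX")
  expect_error(fit_penetrance(two_het, "dominant"), "heterozygote")
  empty <- count_table(c("AA", "AG", "GG"), affected = c(5, 0, 0),
                       unaffected = c(5, 0, 0), loci = "ChrX")
  expect_error(fit_penetrance(empty, "dominant"), "non-empty")
})
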