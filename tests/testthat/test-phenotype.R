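phenotype_header <- paste0("dog_id,sex,neutered,death_age_years,death_cause,",
                           "heart_tests,birth_known,last_known_age_years,Chr1")

test_that("group assignment gives each dog one status and one reason", {
  path <- cohort_csv(header = phenotype_header, rows = c(
    "aff1,m,no,,alive,3.0:1:0,TRUE,,CC",          # DCM -> affected
    "aff2,f,no,4.0,dcm_af,2.0:0:1,TRUE,,CT",      # AF, died young -> affected
    "un_m,m,no,,alive,7.0:0:0,TRUE,,CC",          # clean after 6.5 -> unaffected
    "ex_f,f,no,,alive,7.0:0:0,TRUE,,CC",          # clean but before 8.5
    "ex_edge,m,no,,alive,6.5:0:0,TRUE,,CC",       # exactly at threshold -> excluded
    "ex_died,m,no,5.0,other,4.0:0:0,TRUE,,CC",    # died before threshold
    "ex_unk,m,no,,alive,4.0:0:0,FALSE,,CC",       # birth date unknown
    "ex_nt,f,no,,alive,7.0:0:0,TRUE,10.0,CC"))    # alive at 10, untested since 8.5
  co <- read_cohort(path)
  a <- assign_groups(co)
  expect_equal(a$status,
               c("affected", "affected", "unaffected", "excluded", "excluded",
                 "excluded", "excluded", "excluded"))
  expect_equal(a$affected_ids, c("aff1", "aff2"))
  expect_equal(a$unaffected_ids, "un_m")
  expect_equal(unname(a$excluded[c("ex_died", "ex_unk", "ex_nt")]),
               c("died_before_threshold", "unknown_age",
                 "not_tested_since_threshold"))
  # ex_f's observation age equals its last test (7.0 <= 8.5): under threshold
  expect_equal(unname(a$excluded["ex_f"]), "under_threshold")
  expect_equal(a$n_affected, 2L)
  expect_equal(a$n_unaffected, 1L)
  expect_false(any(is.na(a$reason[a$status == "excluded"])))
  expect_true(all(is.na(a$reason[a$status != "excluded"])))

  # a stricter policy is a parameter change: raise the male age to 7.5
  strict <- assign_groups(co, grouping_policy(male_unaffected_min_age = 7.5))
  expect_equal(strict$n_unaffected, 0L)
})

test_that("AF-DCM summary computes lags, durations and the pooled t-test", {
  path <- cohort_csv(header = phenotype_header, rows = c(
    "d1,m,no,,alive,3.0:0:1;3.5:1:1,TRUE,,CC",    # lag 0.5
    "d2,m,no,,alive,2.0:0:1;3.0:1:1,TRUE,,CC",    # lag 1.0
    "d3,f,no,,alive,4.0:0:1;5.5:1:1,TRUE,,CC",    # lag 1.5
    "d4,m,no,,alive,3.0:1:1,TRUE,,CC",            # simultaneous (lag 0)
    "d5,m,no,,alive,2.0:0:1;3.0:0:1,TRUE,,CC",    # AF only, duration 1
    "d6,f,no,,alive,2.0:0:1;4.0:0:1,TRUE,,CC",    # AF only, duration 2
    "d7,m,no,,alive,2.0:0:1;5.0:0:1,TRUE,,CC",    # AF only, duration 3
    "d8,f,no,,alive,6.0:1:0,TRUE,,CC"))           # DCM without AF
  co <- read_cohort(path)
  s <- summarize_af_dcm(co, include_simultaneous = FALSE)
  expect_equal(s$n_dcm, 5L)
  expect_equal(s$n_dcm_and_af, 4L)
  expect_equal(s$n_simultaneous, 1L)
  expect_equal(s$n_af_only, 3L)
  expect_equal(sort(s$af_to_dcm_lags), c(0, 0.5, 1, 1.5))
  expect_equal(sort(s$af_only_durations), c(1, 2, 3))
  # hand-computed pooled-variance t on {0.5, 1, 1.5} vs {1, 2, 3}
  expect_equal(s$t_statistic, pooled_t_oracle(c(0.5, 1, 1.5), c(1, 2, 3)))
  expect_equal(s$t_statistic, -1.549193, tolerance = 1e-6)
  expect_true(s$t_test_defined)

  s_all <- summarize_af_dcm(co)   # include the simultaneous lag of 0
  expect_equal(s_all$t_statistic,
               pooled_t_oracle(c(0, 0.5, 1, 1.5), c(1, 2, 3)))

  # degenerate sample: t undefined but counts still reported
  s1 <- summarize_af_dcm(co[co$dog_id %in% c("d1", "d5"), ])
  expect_false(s1$t_test_defined)
  expect_true(is.na(s1$t_statistic) && is.na(s1$p_value))
})

test_that("sex onset comparison matches the textbook pooled t", {
  path <- cohort_csv(header = phenotype_header, rows = c(
    "m1,m,no,,alive,4.0:1:0,TRUE,,CC",
    "m2,m,no,,alive,5.0:0:1,TRUE,,CC",
    "f1,f,no,,alive,6.0:1:0,TRUE,,CC",
    "f2,f,no,,alive,3.0:0:0;7.0:1:1,TRUE,,CC",
    "m3,m,no,,alive,8.0:1:0,TRUE,,CC"))  # late, diagnosed at first-ever test
  co <- read_cohort(path)
  full <- sex_onset_comparison(co)
  expect_equal(full$n_male, 3L)
  expect_equal(full$mean_male, mean(c(4, 5, 8)))

  sens <- sex_onset_comparison(co, exclude_untested_late_diagnoses = TRUE)
  expect_equal(sens$n_male, 2L)
  expect_equal(sens$t, pooled_t_oracle(c(4, 5), c(6, 7)))
  expect_equal(sens$t, -2.828427, tolerance = 1e-6)
  expect_equal(sens$mean_male, 4.5)
  expect_equal(sens$mean_female, 6.5)
})

test_that("sex proportion test is the uncorrected Pearson chi-square", {
  tab <- matrix(c(20, 10, 30, 40), nrow = 2)  # male 20/30, female 10/40
  res <- sex_proportion_test(tab)
  expect_equal(res$chi2, 100 / 21, tolerance = 1e-12)  # 4.7619 by hand
  expect_equal(res$df, 1)
  expect_equal(res$p, pchisq(100 / 21, 1, lower.tail = FALSE))
  expect_error(sex_proportion_test(matrix(c(0, 0, 3, 4), 2)), "marginal")
})

test_that("onset quantile thresholds come from binned cumulative counts", {
  rows <- c(sprintf("m%d,m,no,,alive,%s:1:0,TRUE,,CC", 1:5,
                    c("2.0", "2.0", "2.0", "2.0", "9.0")),
            sprintf("f%d,f,no,,alive,%s:1:0,TRUE,,CC", 1:5,
                    c("1.0", "2.0", "3.0", "4.0", "5.0")))
  co <- read_cohort(cohort_csv(header = phenotype_header, rows = rows))
  # males: 4/5 = 80% diagnosed by 2.0 years
  expect_equal(onset_quantile_threshold(co, "male"), 2.0)
  # females: 80% reached at the 4.0-year bin edge
  expect_equal(onset_quantile_threshold(co, "female"), 4.0)
  # a 90% policy shifts both thresholds up
  p90 <- grouping_policy(quantile = 0.9)
  expect_equal(onset_quantile_threshold(co, "male", p90), 9.0)
  expect_equal(onset_quantile_threshold(co, "female", p90), 5.0)
})
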