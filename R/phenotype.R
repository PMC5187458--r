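#' Grouping policy for affected/unaffected assignment
#'
#' Sex-specific minimum ages for inclusion in the unaffected group, plus the
#' quantile and age-bin width used to derive those thresholds from onset
#' ages.  The defaults are the study's: a female counts as unaffected only
#' with a clean heart test after 8.5 years, a male after 6.5 years — the
#' ages by which 80% of ultimately affected dogs of each sex had been
#' diagnosed.  A stricter 90% policy is a parameter change, not a code
#' change.
#'
#' @param female_unaffected_min_age,male_unaffected_min_age years.
#' @param quantile onset quantile defining the thresholds (default 0.8).
#' @param age_bin bin width in years used when deriving thresholds
#'   (default 0.5).
#' @return A `grouping_policy` object.
#' @export
grouping_policy <- function(female_unaffected_min_age = 8.5,
                            male_unaffected_min_age = 6.5,
                            quantile = 0.8, age_bin = 0.5) {
  stopifnot(female_unaffected_min_age > 0, male_unaffected_min_age > 0,
            quantile > 0, quantile < 1, age_bin > 0)
  structure(list(female_unaffected_min_age = female_unaffected_min_age,
                 male_unaffected_min_age = male_unaffected_min_age,
                 quantile = quantile, age_bin = age_bin),
            class = "grouping_policy")
}

#' Assign dogs to affected / unaffected / excluded groups
#'
#' Any dog ever diagnosed with DCM or AF is affected, regardless of age.  A
#' never-diagnosed dog is unaffected if it had a clean heart test after its
#' sex-specific age threshold.  Every other dog is excluded with exactly one
#' reason, chosen by the first match in the order `unknown_age`,
#' `died_before_threshold`, `under_threshold`, `not_tested_since_threshold`.
#'
#' @param cohort a `dcm_cohort`.
#' @param policy a [grouping_policy].
#' @return A `group_assignment`: list with `status` (character vector
#'   aligned to the cohort: affected/unaffected/excluded), `reason`
#'   (exclusion reason or `NA`), `affected_ids`, `unaffected_ids`,
#'   `excluded` (named character vector reason by dog_id), and counts
#'   `n_affected`, `n_unaffected`.
#' @export
assign_groups <- function(cohort, policy = grouping_policy()) {
  stopifnot(inherits(cohort, "dcm_cohort"), inherits(policy, "grouping_policy"))
  ages <- cohort_ages(cohort)
  affected <- !is.na(ages$first_dcm_age) | !is.na(ages$first_af_age)
  thr <- ifelse(cohort$sex == "female", policy$female_unaffected_min_age,
                policy$male_unaffected_min_age)
  clean_after <- !affected & !is.na(ages$last_test_age) & ages$last_test_age > thr
  status <- ifelse(affected, "affected",
                   ifelse(clean_after, "unaffected", "excluded"))
  reason <- rep(NA_character_, nrow(cohort))
  for (i in which(status == "excluded")) {
    reason[i] <-
      if (!cohort$birth_known[i] ||
          (is.na(cohort$last_known_age_years[i]) &&
           is.na(ages$last_test_age[i]))) "unknown_age"
      else if (!is.na(cohort$death_age_years[i]) &&
               cohort$death_age_years[i] <= thr[i]) "died_before_threshold"
      else if (!is.na(cohort$last_known_age_years[i]) &&
               cohort$last_known_age_years[i] <= thr[i]) "under_threshold"
      else "not_tested_since_threshold"
  }
  structure(list(status = status, reason = reason,
                 affected_ids = cohort$dog_id[status == "affected"],
                 unaffected_ids = cohort$dog_id[status == "unaffected"],
                 excluded = stats::setNames(reason[status == "excluded"],
                                            cohort$dog_id[status == "excluded"]),
                 n_affected = sum(status == "affected"),
                 n_unaffected = sum(status == "unaffected"),
                 policy = policy),
            class = "group_assignment")
}

#' @export
print.group_assignment <- function(x, ...) {
  cat(sprintf("Group assignment: %d affected, %d unaffected, %d excluded\n",
              x$n_affected, x$n_unaffected, length(x$excluded)))
  if (length(x$excluded)) print(table(x$excluded))
  invisible(x)
}

#' Summarise the AF-DCM diagnostic relationship
#'
#' For dogs diagnosed with both disorders, the lag from first AF diagnosis
#' to first DCM diagnosis; for dogs diagnosed only with AF, the time from
#' first AF diagnosis to the most recent heart test.  A two-sample t-test
#' compares the two duration samples (a short AF-only follow-up that is not
#' longer than typical AF-to-DCM lags is consistent with AF being a DCM
#' precursor).  A DCM diagnosis at or before the first AF diagnosis counts
#' as a simultaneous diagnosis (lag 0).
#'
#' @param cohort a `dcm_cohort`.
#' @param include_simultaneous include zero lags of simultaneous diagnoses
#'   in the t-test sample (default TRUE, the literal reading of "time from
#'   AF diagnosis to DCM diagnosis"; FALSE restricts to strictly positive
#'   lags).
#' @param welch use Welch's t-test instead of pooled-variance Student's.
#' @return An `af_dcm_summary` list: `n_dcm`, `n_dcm_and_af`,
#'   `n_simultaneous`, `n_af_only`, `af_to_dcm_lags`, `af_only_durations`,
#'   `t_statistic`, `p_value` (both `NA` with a flag if either sample has
#'   fewer than 2 observations).
#' @export
summarize_af_dcm <- function(cohort, include_simultaneous = TRUE,
                             welch = FALSE) {
  ages <- cohort_ages(cohort)
  has_dcm <- !is.na(ages$first_dcm_age)
  has_af <- !is.na(ages$first_af_age)
  dual <- has_dcm & has_af
  lags <- pmax(0, ages$first_dcm_age[dual] - ages$first_af_age[dual])
  af_only <- has_af & !has_dcm
  durations <- ages$last_test_age[af_only] - ages$first_af_age[af_only]
  tol <- 1e-9
  sample_lags <- if (include_simultaneous) lags else lags[lags > tol]
  tt <- if (length(sample_lags) >= 2L && length(durations) >= 2L)
    stats::t.test(sample_lags, durations, var.equal = !welch)
  else NULL
  structure(list(n_dcm = sum(has_dcm), n_dcm_and_af = sum(dual),
                 n_simultaneous = sum(lags <= tol),
                 n_af_only = sum(af_only),
                 af_to_dcm_lags = lags, af_only_durations = durations,
                 t_statistic = if (is.null(tt)) NA_real_ else unname(tt$statistic),
                 p_value = if (is.null(tt)) NA_real_ else tt$p.value,
                 t_test_defined = !is.null(tt)),
            class = "af_dcm_summary")
}

#' @export
print.af_dcm_summary <- function(x, ...) {
  cat(sprintf("DCM cases: %d; with AF: %d (%.1f%%); simultaneous: %d; AF only: %d\n",
              x$n_dcm, x$n_dcm_and_af,
              if (x$n_dcm) 100 * x$n_dcm_and_af / x$n_dcm else NA,
              x$n_simultaneous, x$n_af_only))
  if (x$t_test_defined)
    cat(sprintf("lag vs AF-only duration: t = %.2f, p = %.2g\n",
                x$t_statistic, x$p_value))
  invisible(x)
}

#' Onset-age quantile threshold for one sex
#'
#' Onset ages of ever-affected dogs of the given sex are binned (bin upper
#' edges at multiples of `policy$age_bin`); returns the smallest bin upper
#' edge by which at least `policy$quantile` of affected dogs had been
#' diagnosed.  With the defaults this reproduces the construction behind
#' the 6.5-year (male) and 8.5-year (female) unaffected-inclusion ages.
#'
#' @param cohort a `dcm_cohort`.
#' @param sex `"male"` or `"female"`.
#' @param policy a [grouping_policy] (supplies `quantile` and `age_bin`).
#' @return Threshold age in years.
#' @export
onset_quantile_threshold <- function(cohort, sex = c("male", "female"),
                                     policy = grouping_policy()) {
  sex <- match.arg(sex)
  onsets <- onset_ages(cohort)
  onsets <- onsets$onset[onsets$sex == sex]
  if (!length(onsets)) stop("no affected dogs of sex ", sex)
  bin <- policy$age_bin
  edges <- seq(bin, (ceiling(max(onsets) / bin) + 1) * bin, by = bin)
  cum <- vapply(edges, function(e) mean(onsets <= e + 1e-9), numeric(1))
  edges[which(cum >= policy$quantile)[1L]]
}

# onset = age at first diagnosis of either disorder, for affected dogs
onset_ages <- function(cohort) {
  ages <- cohort_ages(cohort)
  onset <- pmin(ages$first_dcm_age, ages$first_af_age, na.rm = TRUE)
  keep <- !is.na(ages$first_dcm_age) | !is.na(ages$first_af_age)
  first_test <- vapply(cohort$heart_tests, function(ht)
    if (nrow(ht)) min(ht$age) else NA_real_, numeric(1))
  data.frame(dog_id = cohort$dog_id[keep], sex = cohort$sex[keep],
             onset = onset[keep],
             diagnosed_at_first_test = (onset <= first_test + 1e-9)[keep],
             stringsAsFactors = FALSE)
}

#' Compare onset age between the sexes
#'
#' Two-sample t-test on age at first DCM/AF diagnosis, males vs females.
#'
#' @param cohort a `dcm_cohort`.
#' @param exclude_untested_late_diagnoses drop dogs first diagnosed after
#'   `late_age` at their very first heart test (their true onset age is
#'   uncertain); the sensitivity variant of the comparison.
#' @param late_age cut-off for the exclusion (default 6.5 years).
#' @param welch use Welch's t-test instead of pooled-variance Student's.
#' @return List with `t`, `p`, `mean_male`, `mean_female`, `n_male`,
#'   `n_female`.
#' @export
sex_onset_comparison <- function(cohort, exclude_untested_late_diagnoses = FALSE,
                                 late_age = 6.5, welch = FALSE) {
  on <- onset_ages(cohort)
  if (exclude_untested_late_diagnoses)
    on <- on[!(on$onset > late_age & on$diagnosed_at_first_test), , drop = FALSE]
  m <- on$onset[on$sex == "male"]
  f <- on$onset[on$sex == "female"]
  if (length(m) < 2L || length(f) < 2L)
    stop("need at least 2 affected dogs of each sex")
  tt <- stats::t.test(m, f, var.equal = !welch)
  list(t = unname(tt$statistic), p = tt$p.value,
       mean_male = mean(m), mean_female = mean(f),
       n_male = length(m), n_female = length(f))
}

#' Test equality of affected proportions between the sexes
#'
#' Pearson chi-square (no continuity correction) on the 2x2 table of
#' affected/unaffected status by sex.
#'
#' @param x a `dcm_cohort` (affected = ever diagnosed, unaffected = all
#'   other dogs) or a 2x2 matrix of counts.
#' @return List with `chi2`, `df`, `p`.
#' @export
sex_proportion_test <- function(x) {
  tab <- if (is.matrix(x)) x else {
    stopifnot(inherits(x, "dcm_cohort"))
    ages <- cohort_ages(x)
    affected <- !is.na(ages$first_dcm_age) | !is.na(ages$first_af_age)
    table(factor(x$sex, levels = c("male", "female")),
          factor(affected, levels = c(TRUE, FALSE)))
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero marginal in the 2x2 table")
  ct <- stats::chisq.test(tab, correct = FALSE)
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}
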