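#' Define one simulated locus
#'
#' @param locus_name column name, e.g. `"Chr1"`.
#' @param alleles character vector of the two alleles.
#' @param risk_allele which allele carries risk (its frequency is
#'   `allele_freq`).
#' @param allele_freq risk-allele frequency in \[0, 1\] (HWE genotypes).
#' @param model penetrance model kind, see [penetrance_vector].
#' @param f0 baseline risk of the least risky homozygote.
#' @param gamma penetrance parameter (>= 1: the risk allele raises risk).
#' @return A `sim_locus` list.
#' @export
sim_locus <- function(locus_name, alleles, risk_allele, allele_freq,
                      model = "multiplicative", f0 = 0.25, gamma = 1.5) {
  stopifnot(length(alleles) == 2L, risk_allele %in% alleles,
            allele_freq >= 0, allele_freq <= 1, f0 > 0, f0 <= 1, gamma >= 1)
  structure(list(locus_name = locus_name, alleles = alleles,
                 risk_allele = risk_allele, allele_freq = allele_freq,
                 model = model, f0 = f0, gamma = gamma),
            class = "sim_locus")
}

default_sim_loci <- function() {
  # emulates the study panel: study allele frequencies, the selected model
  # kinds, and per-locus baselines whose independent-OR combination gives a
  # lifetime disease probability near the observed 0.76 classified risk
  list(sim_locus("Chr1", c("C", "T"), "C", 0.82, "multiplicative", 0.25, 1.3),
       sim_locus("Chr10", c("A", "C"), "C", 0.06, "multiplicative", 0.25, 1.2),
       sim_locus("Chr15", c("C", "A"), "A", 0.37, "dominant", 0.25, 1.2),
       sim_locus("Chr21", c("G", "A"), "G", 0.58, "dominant", 0.25, 1.35),
       sim_locus("Chr37", c("G", "A"), "A", 0.41, "recessive", 0.25, 1.4))
}

#' Simulation configuration
#'
#' Defaults emulate the study cohort: sex ratio ~0.65 female, male/female
#' onset-age means 4.82/6.14 years with sd 2.0, 58.6% of dual diagnoses
#' simultaneous, AF at most 3 years before DCM, annual heart screening from
#' 1.5 years, competing mortality at 0.1/year, 8% per-call genotyping
#' dropout, and the five-locus panel of [default_sim_loci] under
#' Hardy-Weinberg equilibrium.
#'
#' @param n_dogs cohort size.
#' @param seed integer seed; the same config + seed reproduces the cohort
#'   byte-for-byte.
#' @param sex_ratio_female proportion female.
#' @param loci list of [sim_locus] definitions.
#' @param combine_rule `"independent_or"` (disease probability
#'   `1 - prod(1 - p_l)`) or `"product_capped"`
#'   (`min(1, f0_base * prod(p_l / f0_l))` with `f0_base` the mean per-locus
#'   baseline; capping is reported via a message).
#' @param onset_mean_male,onset_sd_male,onset_mean_female,onset_sd_female
#'   truncated-normal DCM onset-age parameters (years).
#' @param af_simultaneous_prob probability AF is diagnosed at the same time
#'   as DCM.
#' @param af_lead_max_years maximum AF lead time before DCM.
#' @param other_death_hazard exponential rate of death from other causes.
#' @param test_schedule_start,test_interval heart-test schedule (years).
#' @param study_end_age censoring age (years).
#' @param genotype_missing_rate per-call dropout probability.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_dogs = 500L, seed = 1L, sex_ratio_female = 0.65,
                       loci = default_sim_loci(),
                       combine_rule = c("independent_or", "product_capped"),
                       onset_mean_male = 4.82, onset_sd_male = 2.0,
                       onset_mean_female = 6.14, onset_sd_female = 2.0,
                       af_simultaneous_prob = 0.586, af_lead_max_years = 3,
                       other_death_hazard = 0.1,
                       test_schedule_start = 1.5, test_interval = 1,
                       study_end_age = 12, genotype_missing_rate = 0.08) {
  combine_rule <- match.arg(combine_rule)
  stopifnot(n_dogs >= 1, sex_ratio_female >= 0, sex_ratio_female <= 1,
            length(loci) >= 1, onset_sd_male > 0, onset_sd_female > 0,
            af_simultaneous_prob >= 0, af_simultaneous_prob <= 1,
            af_lead_max_years >= 0, other_death_hazard > 0,
            test_interval > 0, study_end_age > test_schedule_start,
            genotype_missing_rate >= 0, genotype_missing_rate < 1)
  structure(list(n_dogs = as.integer(n_dogs), seed = as.integer(seed),
                 sex_ratio_female = sex_ratio_female, loci = loci,
                 combine_rule = combine_rule,
                 onset_mean_male = onset_mean_male,
                 onset_sd_male = onset_sd_male,
                 onset_mean_female = onset_mean_female,
                 onset_sd_female = onset_sd_female,
                 af_simultaneous_prob = af_simultaneous_prob,
                 af_lead_max_years = af_lead_max_years,
                 other_death_hazard = other_death_hazard,
                 test_schedule_start = test_schedule_start,
                 test_interval = test_interval,
                 study_end_age = study_end_age,
                 genotype_missing_rate = genotype_missing_rate),
            class = "sim_config")
}

# genotype label from copies of the risk allele (canonical order)
geno_label <- function(locus, copies) {
  other <- setdiff(locus$alleles, locus$risk_allele)
  lab <- c(paste0(other, other),
           paste0(locus$risk_allele, other),
           paste0(locus$risk_allele, locus$risk_allele))[copies + 1L]
  canonical_genotype(lab)
}

# per-individual penetrance at one locus given risk-allele copies 0/1/2;
# orientation: with gamma >= 1 the risk-allele homozygote is A/A
locus_penetrance <- function(locus, copies) {
  pen <- penetrance_vector(locus$model, locus$f0, locus$gamma)
  unname(pen[copies + 1L])
}

combine_penetrance <- function(pmat, loci, rule) {
  if (rule == "independent_or") return(1 - apply(1 - pmat, 1L, prod))
  f0s <- vapply(loci, `[[`, numeric(1), "f0")
  raw <- mean(f0s) * apply(sweep(pmat, 2L, f0s, `/`), 1L, prod)
  if (any(raw > 1))
    message(sum(raw > 1), " combined penetrance value(s) capped at 1")
  pmin(1, raw)
}

rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

#' Simulate a cohort of dogs
#'
#' Genotypes are drawn per locus under Hardy-Weinberg equilibrium; each
#' dog's lifetime disease indicator is Bernoulli at the combined penetrance
#' of its multi-locus genotype; diseased dogs get a DCM onset age from a
#' sex-specific truncated normal and an AF onset equal to the DCM onset
#' with probability `af_simultaneous_prob`, otherwise earlier by up to
#' `af_lead_max_years`; death from other causes is exponential; heart tests
#' sit on the fixed schedule and diagnosis flags appear at the first test at
#' or after the true onset; events after death or study end are censored
#' (which is how AF-without-DCM dogs arise); genotype calls are masked
#' independently at the dropout rate.  Fully reproducible from
#' `config$seed`.
#'
#' @param config a [sim_config].
#' @return A `dcm_cohort` data.frame (see [read_cohort]); the true onset
#'   ages and disease indicators are attached as attribute `"truth"`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_dogs
  sex <- ifelse(stats::runif(n) < config$sex_ratio_female, "female", "male")
  neutered <- sample(c("yes", "no"), n, replace = TRUE)

  copies <- sapply(config$loci, function(l) stats::rbinom(n, 2L, l$allele_freq))
  copies <- matrix(copies, nrow = n)
  pmat <- sapply(seq_along(config$loci), function(j)
    locus_penetrance(config$loci[[j]], copies[, j]))
  pmat <- matrix(pmat, nrow = n)
  p_disease <- combine_penetrance(pmat, config$loci, config$combine_rule)
  diseased <- stats::runif(n) < p_disease

  onset_mean <- ifelse(sex == "female", config$onset_mean_female,
                       config$onset_mean_male)
  onset_sd <- ifelse(sex == "female", config$onset_sd_female,
                     config$onset_sd_male)
  dcm_onset <- round(rtruncnorm1(n, onset_mean, onset_sd, 1,
                                 config$study_end_age), 3)
  simultaneous <- stats::runif(n) < config$af_simultaneous_prob
  lead <- round(stats::runif(n, 0, config$af_lead_max_years), 3)
  af_onset <- ifelse(simultaneous, dcm_onset, pmax(0, dcm_onset - lead))
  dcm_onset[!diseased] <- NA
  af_onset[!diseased] <- NA

  death_other <- round(stats::rexp(n, config$other_death_hazard), 3)
  obs_end <- pmin(death_other, config$study_end_age)
  died <- death_other < config$study_end_age

  schedule <- seq(config$test_schedule_start, config$study_end_age,
                  by = config$test_interval)
  heart_tests <- lapply(seq_len(n), function(i) {
    ages <- schedule[schedule <= obs_end[i] + 1e-9]
    data.frame(age = ages,
               dcm = !is.na(dcm_onset[i]) & ages >= dcm_onset[i] - 1e-9,
               af = !is.na(af_onset[i]) & ages >= af_onset[i] - 1e-9)
  })

  miss <- matrix(stats::runif(n * length(config$loci)) <
                   config$genotype_missing_rate, nrow = n)
  out <- data.frame(
    dog_id = sprintf("dog%05d", seq_len(n)), sex = sex, neutered = neutered,
    birth_known = TRUE,
    last_known_age_years = round(obs_end, 3),
    death_age_years = ifelse(died, round(death_other, 3), NA_real_),
    death_cause = ifelse(died, "other", "alive"),
    stringsAsFactors = FALSE)
  out$heart_tests <- heart_tests
  loci_names <- vapply(config$loci, `[[`, character(1), "locus_name")
  for (j in seq_along(config$loci)) {
    g <- geno_label(config$loci[[j]], copies[, j])
    g[miss[, j]] <- NA_character_
    out[[loci_names[j]]] <- g
  }
  structure(out, loci = loci_names,
            truth = data.frame(diseased = diseased, dcm_onset = dcm_onset,
                               af_onset = af_onset,
                               p_disease = p_disease),
            problems = data.frame(dog_id = character(0),
                                  problem = character(0)),
            class = c("dcm_cohort", "data.frame"))
}

#' Simulate a case/control genotype count table directly
#'
#' Fast path that skips ages and censoring: genotype (combination) counts
#' for a fixed number of cases and controls are drawn from the exact
#' case/control genotype distributions implied by HWE priors and the
#' penetrance model, via Bayes inversion
#' (`P(g | case) = HWE(g) pen(g) / sum(...)`).
#'
#' @param loci list of [sim_locus] definitions (1-3 loci).
#' @param n_affected,n_unaffected positive counts to draw.
#' @param seed integer seed.
#' @param combine_rule see [sim_config] (only relevant for > 1 locus).
#' @return A [count_table] with one row per genotype combination.
#' @export
simulate_count_table <- function(loci, n_affected, n_unaffected, seed = 1L,
                                 combine_rule = "independent_or") {
  if (inherits(loci, "sim_locus")) loci <- list(loci)
  stopifnot(length(loci) >= 1L, length(loci) <= 3L,
            n_affected > 0, n_unaffected > 0)
  set.seed(seed)
  grids <- rep(list(0:2), length(loci))
  combos <- expand.grid(grids)
  prior <- rep(1, nrow(combos))
  pmat <- matrix(NA_real_, nrow(combos), length(loci))
  gmat <- matrix(NA_character_, nrow(combos), length(loci))
  for (j in seq_along(loci)) {
    l <- loci[[j]]
    c_j <- combos[[j]]
    prior <- prior * stats::dbinom(c_j, 2L, l$allele_freq)
    pmat[, j] <- locus_penetrance(l, c_j)
    gmat[, j] <- geno_label(l, c_j)
  }
  pen <- combine_penetrance(pmat, loci, combine_rule)
  p_case <- prior * pen
  p_ctrl <- prior * (1 - pen)
  if (sum(p_case) <= 0 || sum(p_ctrl) <= 0)
    stop("degenerate case/control genotype distribution")
  aff <- stats::rmultinom(1L, n_affected, p_case / sum(p_case))[, 1L]
  una <- stats::rmultinom(1L, n_unaffected, p_ctrl / sum(p_ctrl))[, 1L]
  count_table(as.data.frame(gmat, stringsAsFactors = FALSE),
              affected = aff, unaffected = una,
              loci = vapply(loci, `[[`, character(1), "locus_name"))
}
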