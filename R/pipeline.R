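#' Cumulative onset curve by sex
#'
#' Cumulative percentage of ultimately affected dogs diagnosed at or before
#' each half-year age bin, per sex — the tabular analogue of the onset
#' figure used to pick the unaffected-inclusion ages.
#'
#' @param cohort a `dcm_cohort`.
#' @param age_bin bin width in years.
#' @return data.frame with `sex`, `age` (bin upper edge), `cum_percent`.
#' @export
onset_cumulative_curve <- function(cohort, age_bin = 0.5) {
  on <- onset_ages(cohort)
  if (!nrow(on)) stop("no affected dogs")
  edges <- seq(age_bin, (ceiling(max(on$onset) / age_bin)) * age_bin,
               by = age_bin)
  do.call(rbind, lapply(c("male", "female"), function(s) {
    o <- on$onset[on$sex == s]
    if (!length(o)) return(NULL)
    data.frame(sex = s, age = edges,
               cum_percent = vapply(edges, function(e)
                 100 * mean(o <= e + 1e-9), numeric(1)))
  }))
}

pool_rule_for_model <- function(kind) {
  switch(kind,
         dominant = pooling_rule("dominant"),
         recessive = pooling_rule("recessive"),
         pooling_rule("small_count", min_count = 5L))
}

#' Run the full association pipeline
#'
#' Phenotype summary, group assignment, per-locus genotype tabulation,
#' penetrance-model selection, model-matched association testing with
#' Bonferroni correction, genotype relative risks against the population
#' risk, and pairwise plus full multi-locus combination analysis over the
#' individually significant loci.
#'
#' Input is either a cohort (`cohort`), from which everything is derived, or
#' pre-tabulated single-locus count tables (`single_tables`, optionally with
#' `multilocus_tables` for the combination stages, since combination counts
#' cannot be recovered from single-locus margins).
#'
#' @param cohort a `dcm_cohort`, or `NULL`.
#' @param single_tables named list of single-locus [count_table]s (ignored
#'   when `cohort` is given).
#' @param multilocus_tables optional named list of combination
#'   [count_table]s for the table-input path; names are ignored, loci are
#'   read from each table.
#' @param policy a [grouping_policy].
#' @param family_single Bonferroni family for single-locus tests (default:
#'   number of loci tested).
#' @param family_pairs Bonferroni family for pair tests (default: number of
#'   pairs formed).
#' @param population optional `c(affected, total)` override for the
#'   relative-risk reference (the assignment's counts otherwise).
#' @param alpha corrected-significance threshold used to pick loci for the
#'   combination stages.
#' @param out_dir optional directory: one delimited file per stage plus a
#'   text report.
#' @return A `dcm_pipeline` list with elements `phenotype`, `assignment`,
#'   `thresholds`, `tables`, `selection`, `association`, `significant`,
#'   `risks`, `pairs`, `triple`, `population`, `settings`.
#' @export
run_pipeline <- function(cohort = NULL, single_tables = NULL,
                         multilocus_tables = NULL,
                         policy = grouping_policy(),
                         family_single = NULL, family_pairs = NULL,
                         population = NULL, alpha = 0.05, out_dir = NULL) {
  phenotype <- assignment <- thresholds <- NULL
  if (!is.null(cohort)) {
    stopifnot(inherits(cohort, "dcm_cohort"))
    if (!nrow(cohort)) stop("empty cohort")
    phenotype <- summarize_af_dcm(cohort)
    assignment <- assign_groups(cohort, policy)
    thresholds <- c(
      male = tryCatch(onset_quantile_threshold(cohort, "male", policy),
                      error = function(e) NA_real_),
      female = tryCatch(onset_quantile_threshold(cohort, "female", policy),
                        error = function(e) NA_real_))
    loci <- cohort_loci(cohort)
    single_tables <- lapply(loci, function(l)
      tabulate_genotype_counts(cohort, l, assignment))
    names(single_tables) <- loci
    if (is.null(population))
      population <- c(affected = assignment$n_affected,
                      total = assignment$n_affected + assignment$n_unaffected)
  } else {
    if (is.null(single_tables)) stop("need a cohort or single-locus tables")
    names(single_tables) <- vapply(single_tables, function(t)
      ct_loci(t)[1L], character(1))
    if (is.null(population))
      stop("population counts required when no cohort is given")
  }
  population <- stats::setNames(as.numeric(population), c("affected", "total"))
  loci <- names(single_tables)
  if (is.null(family_single)) family_single <- length(single_tables)

  selection <- lapply(single_tables, select_penetrance_model)
  association <- lapply(loci, function(l)
    run_association(single_tables[[l]], selection[[l]]$test_type,
                    family_size = family_single))
  names(association) <- loci
  significant <- loci[vapply(association, function(a)
    a$p_corrected < alpha, logical(1))]

  pooled <- lapply(loci, function(l)
    pool_genotypes(single_tables[[l]], pool_rule_for_model(selection[[l]]$kind)))
  names(pooled) <- loci
  risks <- lapply(loci, function(l) {
    unpooled <- multilocus_risks(single_tables[[l]], population["affected"],
                                 population["total"])
    pl <- multilocus_risks(pooled[[l]], population["affected"],
                           population["total"])
    rbind(unpooled, pl[!pl$genotype %in% unpooled$genotype, , drop = FALSE])
  })
  names(risks) <- loci

  pair_stage <- function(pair_loci) {
    tab <- if (!is.null(cohort))
      cross_tabulate(cohort, assignment, pair_loci,
                     mappings = lapply(pooled[pair_loci], attr, "mapping"))
    else find_multilocus_table(multilocus_tables, pair_loci)
    if (is.null(tab)) return(NULL)
    list(loci = pair_loci, table = tab,
         association = multilocus_association(tab, family_size = fam_pairs),
         risks = multilocus_risks(tab, population["affected"],
                                  population["total"]))
  }
  pairs_idx <- if (length(significant) >= 2L)
    utils::combn(significant, 2L, simplify = FALSE) else list()
  fam_pairs <- if (is.null(family_pairs)) max(1L, length(pairs_idx))
               else family_pairs
  pairs <- Filter(Negate(is.null), lapply(pairs_idx, pair_stage))

  triple <- NULL
  if (length(significant) >= 3L) {
    tri_loci <- significant[1:3]
    tab <- if (!is.null(cohort))
      cross_tabulate(cohort, assignment, tri_loci,
                     mappings = lapply(pooled[tri_loci], attr, "mapping"))
    else find_multilocus_table(multilocus_tables, tri_loci)
    if (!is.null(tab))
      triple <- list(loci = tri_loci, table = tab,
                     association = multilocus_association(tab, family_size = 1L),
                     risks = multilocus_risks(tab, population["affected"],
                                              population["total"]))
  }
  out <- structure(list(phenotype = phenotype, assignment = assignment,
                        thresholds = thresholds, tables = single_tables,
                        pooled = pooled, selection = selection,
                        association = association, significant = significant,
                        risks = risks, pairs = pairs, triple = triple,
                        population = population,
                        settings = list(policy = policy,
                                        family_single = family_single,
                                        family_pairs = fam_pairs,
                                        alpha = alpha,
                                        rr_reference = "population",
                                        expected_counts = "unaffected_proportions",
                                        zero_expected_cells = "skip_keep_df")),
                   class = "dcm_pipeline")
  if (!is.null(out_dir)) write_pipeline(out, out_dir, cohort)
  out
}

find_multilocus_table <- function(tables, loci) {
  if (is.null(tables)) return(NULL)
  for (t in tables)
    if (setequal(ct_loci(t), loci)) return(t)
  NULL
}

write_pipeline <- function(x, out_dir, cohort = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  f <- function(...) file.path(out_dir, ...)
  for (l in names(x$tables))
    write_count_table(x$tables[[l]], f(paste0("counts_", l, ".csv")))
  assoc <- data.frame(
    locus = names(x$association),
    model = vapply(x$selection, `[[`, character(1), "kind"),
    test = vapply(x$association, `[[`, character(1), "test_type"),
    chi2 = vapply(x$association, `[[`, numeric(1), "chi2"),
    df = vapply(x$association, `[[`, numeric(1), "df"),
    p_corrected = vapply(x$association, `[[`, numeric(1), "p_corrected"))
  utils::write.csv(assoc, f("association.csv"), row.names = FALSE)
  for (l in names(x$risks))
    utils::write.csv(as.data.frame(x$risks[[l]]),
                     f(paste0("risks_", l, ".csv")), row.names = FALSE)
  for (p in x$pairs)
    utils::write.csv(as.data.frame(p$risks),
                     f(paste0("risks_", paste(p$loci, collapse = "_"), ".csv")),
                     row.names = FALSE)
  if (!is.null(x$triple))
    utils::write.csv(as.data.frame(x$triple$risks),
                     f("risks_triple.csv"), row.names = FALSE)
  if (!is.null(cohort))
    utils::write.csv(onset_cumulative_curve(cohort), f("onset_curve.csv"),
                     row.names = FALSE)
  rep <- utils::capture.output(print(x))
  writeLines(rep, f("report.txt"))
  invisible(out_dir)
}

#' @export
print.dcm_pipeline <- function(x, ...) {
  cat("=== DCM/AF multi-locus association pipeline ===\n")
  cat("Settings:", paste(sprintf("%s=%s", names(x$settings)[-1],
                                 unlist(x$settings[-1])), collapse = ", "),
      "\n")
  if (!is.null(x$phenotype)) print(x$phenotype)
  if (!is.null(x$assignment)) print(x$assignment)
  if (!is.null(x$thresholds))
    cat(sprintf("Onset thresholds: male %.1f y, female %.1f y\n",
                x$thresholds["male"], x$thresholds["female"]))
  cat(sprintf("Population risk: %d/%d = %.2f\n", x$population["affected"],
              x$population["total"],
              x$population["affected"] / x$population["total"]))
  cat("\n-- Single-locus tests --\n")
  for (l in names(x$association)) {
    a <- x$association[[l]]
    cat(sprintf("%s: %s model -> %s test, chi2 = %.2f (df %d), corrected p = %.2g%s\n",
                l, x$selection[[l]]$kind, a$test_type, a$chi2, a$df,
                a$p_corrected,
                if (l %in% x$significant) " *" else ""))
  }
  for (p in x$pairs) {
    a <- p$association
    cat(sprintf("Pair %s: chi2 = %.2f (df %d), corrected p = %.2g\n",
                paste(p$loci, collapse = "+"), a$chi2, a$df, a$p_corrected))
  }
  if (!is.null(x$triple)) {
    a <- x$triple$association
    cat(sprintf("Triple %s: chi2 = %.2f (df %d), p = %.2g\n",
                paste(x$triple$loci, collapse = "+"), a$chi2, a$df, a$p_raw))
    print(x$triple$risks)
  }
  invisible(x)
}
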