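#' Expected affected counts from unaffected genotype proportions
#'
#' The association machinery used throughout this package tests the observed
#' affected counts against expectations derived from the unaffected group:
#' the proportion of unaffected individuals in each category (genotype,
#' pooled genotype class, allele, or genotype combination) is multiplied by
#' the total number of affected individuals.  This is a goodness-of-fit of
#' the affected distribution against unaffected-derived proportions, not the
#' usual 2xk contingency expectation; see the methods vignette.
#'
#' @param affected,unaffected non-negative per-category counts.
#' @return Numeric vector of expected affected counts; sums exactly to
#'   `sum(affected)`.
#' @examples
#' expected_affected(c(103, 19), c(27, 11))  # 86.68 35.32
#' @export
expected_affected <- function(affected, unaffected) {
  stopifnot(length(affected) == length(unaffected),
            all(affected >= 0), all(unaffected >= 0))
  if (sum(unaffected) == 0) stop("no unaffected individuals: expected counts undefined")
  if (sum(affected) == 0) stop("no affected individuals: nothing to test")
  unaffected / sum(unaffected) * sum(affected)
}

#' Goodness-of-fit chi-square with the zero-expected-cell rule
#'
#' Pearson chi-square `sum((O - E)^2 / E)` over categories with positive
#' expected count.  Categories with expected count zero contribute nothing to
#' the statistic but keep their place in the degrees of freedom
#' (`df = k - 1` over all `k` categories), the convention under which the
#' three-locus combination test in the motivating study reproduces both its
#' statistic and its p-value.
#'
#' @param observed,expected numeric vectors of equal length.
#' @param df_override optional integer to override the default `k - 1`.
#' @return List with `chi2`, `df`, `p`.
#' @export
chisq_gof <- function(observed, expected, df_override = NULL) {
  stopifnot(length(observed) == length(expected))
  if (all(expected == 0)) stop("all expected counts are zero")
  keep <- expected > 0
  chi2 <- sum((observed[keep] - expected[keep])^2 / expected[keep])
  df <- if (is.null(df_override)) length(observed) - 1L else as.integer(df_override)
  list(chi2 = chi2, df = df, p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Bonferroni family correction
#'
#' @param p_raw raw p-value(s) in (0, 1].
#' @param family_size number of tests in the family.
#' @return `min(1, p_raw * family_size)`, vectorised.
#' @export
bonferroni <- function(p_raw, family_size) {
  stopifnot(family_size >= 1)
  pmin(1, p_raw * family_size)
}

# Cochran-Armitage trend statistic on a 2x3 (affected/unaffected x genotype)
# table with scores 0,1,2; genotype order = copies of the risk allele.
cochran_armitage <- function(affected, unaffected, scores = c(0, 1, 2)) {
  stopifnot(length(affected) == length(scores),
            length(unaffected) == length(scores))
  n_i <- affected + unaffected
  N <- sum(n_i)
  R <- sum(affected)
  num <- sum(scores * (affected - n_i * R / N))
  pbar <- R / N
  var <- pbar * (1 - pbar) *
    (sum(scores^2 * n_i) - sum(scores * n_i)^2 / N)
  if (var <= 0) stop("degenerate trend test: zero variance")
  num^2 / var
}

# Split a two-character genotype label into its alleles.
split_genotype <- function(label) {
  if (any(nchar(label) != 2L))
    stop("allelic test needs unpooled two-allele genotype labels, got: ",
         paste(label[nchar(label) != 2L], collapse = ", "))
  strsplit(label, "", fixed = TRUE)
}

# Collapse genotype counts into allele counts (each individual contributes
# two observations).
allele_counts <- function(labels, counts) {
  al <- split_genotype(labels)
  alleles <- sort(unique(unlist(al)))
  out <- stats::setNames(numeric(length(alleles)), alleles)
  for (i in seq_along(labels))
    for (a in al[[i]]) out[a] <- out[a] + counts[i]
  out
}

#' Single- or multi-locus association test
#'
#' Runs the association test matching a penetrance model on a genotype count
#' table, with expected counts from the unaffected proportions
#' ([expected_affected]) and Bonferroni correction over the test family.
#'
#' Test types: `"allelic"` doubles genotype counts into allele space
#' (multiplicative penetrance); `"pooled_dominant"` / `"pooled_recessive"`
#' pool the heterozygote with the like-penetrance homozygote (orientation
#' from the observed risks) and test the two resulting classes;
#' `"trend"` is the Cochran-Armitage test with scores 0,1,2 (additive);
#' `"genotypic"` tests all categories unpooled — the form used for the
#' two- and three-locus combination tables.
#'
#' @param table a [count_table].
#' @param test_type one of `"allelic"`, `"pooled_dominant"`,
#'   `"pooled_recessive"`, `"trend"`, `"genotypic"`.
#' @param family_size number of tests in the Bonferroni family (5 for the
#'   single-locus panel, 3 for the pairs family in the motivating study).
#' @param contingency if `TRUE`, use the standard 2xk contingency
#'   expectation instead of the unaffected-proportion construction
#'   (comparison option; not the default and not what the study used).
#' @return An object of class `assoc_test`: list with `loci`, `test_type`,
#'   `chi2`, `df`, `p_raw`, `p_corrected`, `family_size`,
#'   `risk_allele_or_genotype`, `observed`, `expected`, `labels`.
#' @examples
#' run_association(iwh_count_tables()$chr1, "allelic", family_size = 5)
#' @export
run_association <- function(table, test_type = c("allelic", "pooled_dominant",
                                                 "pooled_recessive", "trend",
                                                 "genotypic"),
                            family_size = 1L, contingency = FALSE) {
  test_type <- match.arg(test_type)
  stopifnot(inherits(table, "count_table"))
  loci <- ct_loci(table)
  labels <- ct_labels(table)

  if (test_type %in% c("pooled_dominant", "pooled_recessive") &&
      nrow(table) > 2L) {
    rule <- if (test_type == "pooled_dominant") "dominant" else "recessive"
    table <- pool_genotypes(table, pooling_rule(rule))
    labels <- ct_labels(table)
  }

  if (test_type == "trend") {
    if (nrow(table) != 3L || any(nchar(labels) != 2L))
      stop("trend test requires an unpooled 3-genotype single-locus table")
    ord <- order_by_risk_allele(labels, table$affected, table$unaffected)
    chi2 <- cochran_armitage(table$affected[ord], table$unaffected[ord])
    df <- 1L
    observed <- table$affected[ord]
    expected <- NULL
    labels <- labels[ord]
  } else {
    if (test_type == "allelic") {
      observed <- allele_counts(labels, table$affected)
      unaff <- allele_counts(labels, table$unaffected)
      labels <- names(observed)
    } else {
      observed <- table$affected
      unaff <- table$unaffected
    }
    if (contingency) {
      # full k x 2 Pearson statistic (both margins random), the calibrated
      # comparison to the unaffected-proportion construction
      tab <- cbind(observed, unaff)
      e_full <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      chi2 <- sum((tab - e_full)^2 / e_full)
      df <- nrow(tab) - 1L
      expected <- e_full[, 1L]
    } else {
      expected <- expected_affected(observed, unaff)
      gof <- chisq_gof(observed, expected)
      chi2 <- gof$chi2
      df <- gof$df
    }
  }
  p_raw <- stats::pchisq(chi2, df, lower.tail = FALSE)
  # category (or allele) observed in excess of expectation among affected
  risk_lab <- if (test_type == "trend") labels[3L] else
    labels[which.max(observed - expected)]
  structure(list(loci = loci, test_type = test_type, chi2 = chi2,
                 df = df, p_raw = p_raw,
                 p_corrected = bonferroni(p_raw, family_size),
                 family_size = as.integer(family_size),
                 risk_allele_or_genotype = risk_lab,
                 observed = observed, expected = expected, labels = labels),
            class = "assoc_test")
}

# Order 3 genotype labels by copies of the risk allele (0,1,2), where the
# risk allele is the one enriched among affected relative to unaffected.
order_by_risk_allele <- function(labels, affected, unaffected) {
  aff <- allele_counts(labels, affected)
  una <- allele_counts(labels, unaffected)
  risk <- names(which.max(aff / sum(aff) - una / sum(una)))
  copies <- vapply(split_genotype(labels),
                   function(a) sum(a == risk), numeric(1))
  order(copies)
}

#' Association test on a multi-locus combination table
#'
#' Convenience wrapper: genotypic test ([run_association]) on a combination
#' count table; degrees of freedom are `rows - 1`, with zero-expected rows
#' skipped in the statistic but counted in the df.
#'
#' @inheritParams run_association
#' @return An `assoc_test` object.
#' @export
multilocus_association <- function(table, family_size = 1L) {
  run_association(table, "genotypic", family_size = family_size)
}

#' @export
print.assoc_test <- function(x, ...) {
  cat(sprintf("%s association test at %s\n", x$test_type,
              paste(x$loci, collapse = " x ")))
  cat(sprintf("  chi2 = %.2f, df = %d, p = %.3g (Bonferroni x%d: %.3g)\n",
              x$chi2, x$df, x$p_raw, x$family_size, x$p_corrected))
  cat("  highest-risk category:", x$risk_allele_or_genotype, "\n")
  invisible(x)
}
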