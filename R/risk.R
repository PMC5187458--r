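#' Genotype pooling rules
#'
#' Pooling of single-locus genotype classes before risk estimation and
#' association testing: under a dominant penetrance model the heterozygote is
#' pooled with the at-risk homozygote (their penetrances are equal); under a
#' recessive model with the least-risky homozygote; `small_count` merges any
#' genotype carried by fewer than `min_count` individuals into the adjacent
#' heterozygote class; `none` is the identity.
#'
#' @param mode one of `"dominant"`, `"recessive"`, `"small_count"`, `"none"`.
#' @param min_count minimum genotype total under `small_count` (default 5,
#'   the threshold used in the motivating study).
#' @return A `pooling_rule` object.
#' @export
pooling_rule <- function(mode = c("none", "dominant", "recessive",
                                  "small_count"), min_count = 5L) {
  mode <- match.arg(mode)
  stopifnot(min_count >= 1)
  structure(list(mode = mode, min_count = as.integer(min_count)),
            class = "pooling_rule")
}

# het label has two distinct characters; pooled labels contain "/"
is_het <- function(label) {
  nchar(label) == 2L & substr(label, 1, 1) != substr(label, 2, 2)
}

#' Pool genotype classes of a single-locus count table
#'
#' @param table a single-locus [count_table] with unpooled genotype labels.
#' @param rule a [pooling_rule].
#' @return A pooled [count_table]; pooled classes are labelled
#'   heterozygote-first (e.g. `"GA/GG"`).  The genotype-to-class mapping is
#'   attached as attribute `"mapping"`.  Counts are conserved exactly.
#' @examples
#' pool_genotypes(iwh_count_tables()$chr37, pooling_rule("recessive"))
#' @export
pool_genotypes <- function(table, rule = pooling_rule()) {
  stopifnot(inherits(table, "count_table"), length(ct_loci(table)) == 1L,
            inherits(rule, "pooling_rule"))
  labels <- ct_labels(table)
  if (rule$mode == "none") {
    attr(table, "mapping") <- stats::setNames(labels, labels)
    return(table)
  }
  het <- which(is_het(labels))
  hom <- which(!is_het(labels))
  if (length(het) != 1L || length(hom) != 2L)
    stop("pooling needs one heterozygote and two homozygote classes, got: ",
         paste(labels, collapse = ", "))
  total <- table$affected + table$unaffected
  risk <- ifelse(total > 0, table$affected / total, NA_real_)
  mapping <- stats::setNames(labels, labels)
  if (rule$mode %in% c("dominant", "recessive")) {
    partner <- if (rule$mode == "dominant") hom[which.max(risk[hom])]
               else hom[which.min(risk[hom])]
    mapping[partner] <- mapping[het] <- paste(labels[het], labels[partner],
                                              sep = "/")
  } else { # small_count
    small_hom <- hom[total[hom] < rule$min_count]
    for (h in small_hom)
      mapping[h] <- mapping[het] <- paste(labels[het], labels[h], sep = "/")
    if (length(small_hom) > 1L)
      stop("pooling would leave a single category")
    if (total[het] < rule$min_count && length(small_hom) == 0L) {
      partner <- hom[which.min(abs(risk[hom] - risk[het]))]
      mapping[partner] <- mapping[het] <- paste(labels[het], labels[partner],
                                                sep = "/")
    }
  }
  cls <- unique(mapping[labels])
  if (length(cls) < 2L) stop("pooling would leave a single category")
  aff <- vapply(cls, function(cl) sum(table$affected[mapping[labels] == cl]),
                numeric(1))
  una <- vapply(cls, function(cl) sum(table$unaffected[mapping[labels] == cl]),
                numeric(1))
  out <- count_table(unname(cls), affected = unname(aff),
                     unaffected = unname(una), loci = ct_loci(table))
  attr(out, "mapping") <- mapping
  out
}

#' Observed genotype risk
#'
#' Disease risk of a genotype class: affected count divided by the total
#' number of individuals carrying the genotype.
#'
#' @param affected affected count(s), or a [count_table].
#' @param total genotype total(s); ignored when `affected` is a table.
#' @return Numeric risk(s) in \[0, 1\].
#' @examples
#' genotype_risk(44, 54)  # 0.8148
#' @export
genotype_risk <- function(affected, total) {
  if (inherits(affected, "count_table")) {
    tab <- affected
    affected <- tab$affected
    total <- tab$affected + tab$unaffected
  }
  stopifnot(all(total > 0))
  affected / total
}

#' Relative risk against the population risk, with log-method CI
#'
#' Relative risk of a genotype (or genotype combination) class versus the
#' whole-population risk, with a log-method confidence interval:
#' `exp(log(rr) -+ z * sqrt(1/a - 1/n + 1/A - 1/N))` where `a/n` are the
#' genotype's affected/total counts and `A/N` the population's.  Following
#' the motivating study, the default reference is the *whole* classified
#' population (which contains the genotype subset), treated as an
#' independent sample; `reference = "complement"` gives the standard
#' disjoint-group comparison instead.
#'
#' @param affected,total genotype-class counts (vectorised).
#' @param population_affected,population_total reference counts
#'   (default the study's 72/95).
#' @param conf confidence level (default 0.95).
#' @param reference `"population"` (study convention) or `"complement"`.
#' @param labels optional genotype labels for the result rows.
#' @return A data.frame of class `risk_estimate` with columns `genotype`,
#'   `affected`, `total`, `risk`, `rr`, `ci_low`, `ci_high`, `significant`
#'   (CI excludes 1).  Rows with `affected == 0` get `rr = 0` and `NA` CI
#'   (no convention exists for them); `significant` is `NA` there.
#' @examples
#' relative_risk(44, 54)                    # Chr1 CC: rr 1.08 (0.91-1.28)
#' relative_risk(13, 14)                    # rr 1.23 (1.02-1.47)
#' @export
relative_risk <- function(affected, total,
                          population_affected = iwh_population()[["affected"]],
                          population_total = iwh_population()[["total"]],
                          conf = 0.95,
                          reference = c("population", "complement"),
                          labels = NULL) {
  reference <- match.arg(reference)
  stopifnot(length(affected) == length(total), all(total > 0),
            population_total > 0, population_affected >= 1)
  if (reference == "complement") {
    ref_a <- population_affected - affected
    ref_n <- population_total - total
    if (any(ref_a < 1) || any(ref_n < 1))
      stop("complement reference group is empty")
  } else {
    ref_a <- rep(population_affected, length(affected))
    ref_n <- rep(population_total, length(affected))
  }
  risk <- affected / total
  rr <- risk / (ref_a / ref_n)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  se <- sqrt(1 / affected - 1 / total + 1 / ref_a - 1 / ref_n)
  lo <- exp(log(rr) - z * se)
  hi <- exp(log(rr) + z * se)
  zero <- affected == 0
  rr[zero] <- 0
  lo[zero] <- hi[zero] <- NA_real_
  out <- data.frame(
    genotype = if (is.null(labels)) rep(NA_character_, length(rr)) else labels,
    affected = affected, total = total, risk = risk,
    rr = rr, ci_low = lo, ci_high = hi,
    significant = ifelse(zero, NA, lo > 1 | hi < 1),
    stringsAsFactors = FALSE)
  structure(out, population = c(affected = unname(population_affected),
                                total = unname(population_total)),
            conf = conf, class = c("risk_estimate", "data.frame"))
}

#' Per-row risk estimates for a (multi-locus) count table
#'
#' One [relative_risk] row per genotype class or combination in the table.
#'
#' @param table a [count_table].
#' @inheritParams relative_risk
#' @return A `risk_estimate` data.frame, one row per table row.
#' @examples
#' multilocus_risks(iwh_count_tables()$chr1_chr21_chr37)
#' @export
multilocus_risks <- function(table,
                             population_affected = iwh_population()[["affected"]],
                             population_total = iwh_population()[["total"]],
                             conf = 0.95) {
  stopifnot(inherits(table, "count_table"))
  relative_risk(table$affected, table$affected + table$unaffected,
                population_affected, population_total, conf = conf,
                labels = ct_labels(table))
}

#' Cross-tabulate genotype combinations over a cohort
#'
#' Builds the affected/unaffected count table over combinations of (pooled)
#' genotype classes at two or three loci.  Dogs in the excluded group or
#' missing a call at any involved locus are omitted.
#'
#' @param cohort a `dcm_cohort` data.frame (see [read_cohort]).
#' @param assignment a [group_assignment] for the cohort.
#' @param loci character vector of 2 or 3 locus (column) names.
#' @param mappings optional named list (per locus) of genotype-to-class
#'   mappings, as attached by [pool_genotypes]; unlisted loci stay unpooled.
#' @return A [count_table] with one row per observed class combination,
#'   ordered lexicographically by class label.
#' @export
cross_tabulate <- function(cohort, assignment, loci, mappings = list()) {
  stopifnot(length(loci) %in% 2:3, all(loci %in% names(cohort)))
  status <- assignment$status
  keep <- status %in% c("affected", "unaffected")
  g <- lapply(loci, function(l) {
    calls <- canonical_genotype(cohort[[l]])
    m <- mappings[[l]]
    if (!is.null(m)) calls <- unname(m[calls])
    calls
  })
  complete <- keep & Reduce(`&`, lapply(g, function(x) !is.na(x) & x != ""))
  if (!any(complete)) stop("no individuals genotyped at all of: ",
                           paste(loci, collapse = ", "))
  g <- lapply(g, function(x) x[complete])
  aff <- status[complete] == "affected"
  key <- do.call(paste, c(g, sep = ":"))
  combos <- sort(unique(key))
  parts <- strsplit(combos, ":", fixed = TRUE)
  gframe <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
  count_table(gframe,
              affected = vapply(combos, function(k) sum(aff & key == k),
                                numeric(1)),
              unaffected = vapply(combos, function(k) sum(!aff & key == k),
                                  numeric(1)),
              loci = loci)
}

#' @export
print.risk_estimate <- function(x, digits = 2, ...) {
  pop <- attr(x, "population")
  cat(sprintf("Risk vs population risk %d/%d = %.2f (%.0f%% CI, log method)\n",
              pop[["affected"]], pop[["total"]],
              pop[["affected"]] / pop[["total"]], 100 * attr(x, "conf")))
  y <- as.data.frame(x)
  y$risk <- round(y$risk, digits); y$rr <- round(y$rr, digits)
  y$ci_low <- round(y$ci_low, digits); y$ci_high <- round(y$ci_high, digits)
  print(y, ...)
  invisible(x)
}
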