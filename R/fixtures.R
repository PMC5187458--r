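#' Published Irish Wolfhound DCM/AF risk tables
#'
#' The study that motivates this package printed, for each genotype (and each
#' two- and three-locus genotype combination) at the significantly associated
#' loci, the observed disease risk, the number of dogs carrying the genotype,
#' and the relative risk against the whole-population risk with its 95% CI.
#' Raw genotype data were not deposited, but the underlying affected counts
#' are exactly recoverable as `round(risk * total)` because risks were printed
#' at two decimals over small totals.  This function returns the printed
#' values; [iwh_count_tables()] returns the reconstructed count tables.
#'
#' @param table optional name to subset: one of `"chr1"`, `"chr21"`,
#'   `"chr37"` (unpooled), `"chr1_pooled"`, `"chr21_pooled"`,
#'   `"chr37_pooled"`, `"chr1_chr21"`, `"chr1_chr37"`, `"chr21_chr37"`,
#'   `"chr1_chr21_chr37"`.
#' @return A data.frame with columns `table`, `g1`--`g3`, `risk`, `total`,
#'   `rr`, `ci_low`, `ci_high` (the last three `NA` where not printed).
#' @export
iwh_risk_tables <- function(table = NULL) {
  path <- system.file("extdata", "published_risk_tables.csv",
                      package = "wolfhoundDCM", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(table)) {
    df <- df[df$table %in% table, , drop = FALSE]
    if (!nrow(df)) stop("unknown table name: ", table)
    rownames(df) <- NULL
  }
  df
}

#' Reconstruct affected/unaffected counts from printed (risk, total) pairs
#'
#' `affected = round(risk * total)`, `unaffected = total - affected`.  A
#' consistency check asserts that the re-computed risk, rounded to two
#' decimals, equals the printed risk for every row; this validates the
#' reconstruction (it holds for every published row).
#'
#' @param risk printed per-genotype risks (2 dp).
#' @param total printed per-genotype totals.
#' @return data.frame with columns `affected`, `unaffected`.
#' @export
reconstruct_counts <- function(risk, total) {
  stopifnot(length(risk) == length(total), all(total > 0))
  affected <- as.integer(round(risk * total))
  bad <- round(affected / total, 2) != round(risk, 2)
  if (any(bad))
    stop("reconstruction inconsistent with printed risk at row(s): ",
         paste(which(bad), collapse = ", "))
  data.frame(affected = affected, unaffected = as.integer(total) - affected)
}

#' Reconstructed genotype count tables for the associated loci
#'
#' Count tables for the three individually significant loci (Chr1, Chr21,
#' Chr37), their pooled forms, the three pairwise combination tables and the
#' three-locus combination table, reconstructed from the printed risk/total
#' pairs via [reconstruct_counts()].
#'
#' @return Named list of [count_table] objects.
#' @examples
#' ct <- iwh_count_tables()$chr1
#' ct$affected   # 44 15 2
#' @export
iwh_count_tables <- function() {
  df <- iwh_risk_tables()
  locus_names <- list(
    chr1 = "Chr1", chr21 = "Chr21", chr37 = "Chr37",
    chr1_pooled = "Chr1", chr21_pooled = "Chr21", chr37_pooled = "Chr37",
    chr1_chr21 = c("Chr1", "Chr21"), chr1_chr37 = c("Chr1", "Chr37"),
    chr21_chr37 = c("Chr21", "Chr37"),
    chr1_chr21_chr37 = c("Chr1", "Chr21", "Chr37"))
  out <- lapply(names(locus_names), function(nm) {
    sub <- df[df$table == nm, , drop = FALSE]
    loci <- locus_names[[nm]]
    cnt <- reconstruct_counts(sub$risk, sub$total)
    g <- sub[, c("g1", "g2", "g3")[seq_along(loci)], drop = FALSE]
    count_table(g, affected = cnt$affected, unaffected = cnt$unaffected,
                loci = loci)
  })
  names(out) <- names(locus_names)
  out
}

#' Classified-population disease counts
#'
#' The affected/total counts of the classified study population (72 affected
#' of 95 classified dogs; overall risk 0.76), the reference for all relative
#' risks.
#'
#' @return Named numeric vector `c(affected = 72, total = 95)`.
#' @export
iwh_population <- function() c(affected = 72, total = 95)

#' PCR-RFLP locus definitions for the Irish Wolfhound SNP panel
#'
#' The five-SNP panel with, per primer set, the restriction enzyme, its
#' recognition site, which allele is cut, the PCR product length and the
#' expected digest fragment sizes.
#'
#' @return A data.frame of class `locus_definitions`; `digest_fragments` is a
#'   list-column of integer fragment sizes.
#' @export
iwh_loci <- function() {
  path <- system.file("extdata", "iwh_loci.csv",
                      package = "wolfhoundDCM", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$digest_fragments <- lapply(strsplit(df$digest_fragments, ";", fixed = TRUE),
                                as.integer)
  class(df) <- c("locus_definitions", "data.frame")
  df
}
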