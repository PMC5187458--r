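#' Validate a PCR-RFLP locus definition
#'
#' Internal consistency check of one locus/primer-set definition: the digest
#' fragment sizes must sum to the PCR product length.  In the packaged
#' Irish Wolfhound panel every definition passes except the Chr21
#' new-forward primer set, whose published fragments (384 + 39) exceed the
#' published 410 bp amplicon by 13 bp; the validator flags it and no
#' correction is assumed.
#'
#' @param locus one row of a `locus_definitions` data.frame (see
#'   [iwh_loci]), or any list with fields `pcr_length` and
#'   `digest_fragments`.
#' @return List with `pass` (logical) and `discrepancy_bp`
#'   (`sum(fragments) - pcr_length`).
#' @export
validate_locus_definition <- function(locus) {
  frg <- locus$digest_fragments
  if (is.list(frg)) frg <- frg[[1L]]
  stopifnot(length(frg) >= 1, all(frg > 0), locus$pcr_length > 0)
  d <- sum(frg) - locus$pcr_length
  list(pass = d == 0, discrepancy_bp = as.integer(d))
}

#' Validate every definition in a locus table
#'
#' @param loci a `locus_definitions` data.frame.
#' @return The table with added columns `pass` and `discrepancy_bp`.
#' @export
validate_loci <- function(loci = iwh_loci()) {
  res <- lapply(seq_len(nrow(loci)), function(i)
    validate_locus_definition(loci[i, , drop = FALSE]))
  loci$pass <- vapply(res, `[[`, logical(1), "pass")
  loci$discrepancy_bp <- vapply(res, `[[`, integer(1), "discrepancy_bp")
  loci
}

# Fragments a gel can be relied on to show: small fragments (< min_visible
# bp) routinely run off or are invisible on 2% agarose, so they are treated
# as optional when matching band patterns.
mandatory_fragments <- function(fragments, min_visible = 40L) {
  fragments[fragments >= min_visible]
}

#' Expected band pattern for a genotype at a locus
#'
#' @param locus one row of a `locus_definitions` table.
#' @param genotype two-character genotype call (e.g. `"CT"`).
#' @return Integer band sizes, sorted decreasing: the full-length product
#'   for each uncut allele copy and/or the digest fragments for cut copies.
#' @export
expected_band_pattern <- function(locus, genotype) {
  frg <- locus$digest_fragments
  if (is.list(frg)) frg <- frg[[1L]]
  alleles <- strsplit(canonical_genotype(genotype), "", fixed = TRUE)[[1L]]
  stopifnot(all(alleles %in% c(locus$allele1, locus$allele2)))
  bands <- integer(0)
  if (any(alleles != locus$cut_allele)) bands <- c(bands, locus$pcr_length)
  if (any(alleles == locus$cut_allele)) bands <- c(bands, frg)
  sort(unique(as.integer(bands)), decreasing = TRUE)
}

#' Call a genotype from an observed restriction-digest band pattern
#'
#' A single band matching the PCR product length means no product was
#' digested: homozygote for the non-cut allele.  Digest fragments with no
#' full-length band mean complete digestion: homozygote for the cut allele.
#' Full-length band plus digest fragments: heterozygote.  Band sizes match
#' within `tolerance_bp`; digest fragments smaller than 40 bp are optional
#' (they are routinely invisible on gel), larger ones are mandatory.  Any
#' observed band matching neither the full-length product nor a digest
#' fragment, or a missing mandatory fragment, gives a no-call with a
#' diagnostic.
#'
#' @param bands observed band sizes in bp.
#' @param locus one row of a `locus_definitions` table.
#' @param tolerance_bp band-size matching tolerance (default 10, roughly
#'   gel resolution in the 100-400 bp range).
#' @return List with `genotype` (canonical two-character call, or `NA` on
#'   no-call) and `diagnostic`.
#' @examples
#' chr1 <- iwh_loci()[1, ]
#' call_genotype_from_bands(c(311), chr1)$genotype            # "TT"
#' call_genotype_from_bands(c(311, 228, 83), chr1)$genotype   # "CT"
#' call_genotype_from_bands(c(228, 83), chr1)$genotype        # "CC"
#' @export
call_genotype_from_bands <- function(bands, locus, tolerance_bp = 10L) {
  if (!length(bands) || any(bands <= 0)) stop("bands must be positive sizes")
  frg <- locus$digest_fragments
  if (is.list(frg)) frg <- frg[[1L]]
  near <- function(x, target) abs(x - target) <= tolerance_bp
  matches_full <- vapply(bands, near, logical(1), target = locus$pcr_length)
  matches_frag <- vapply(bands, function(b) any(near(b, frg)), logical(1))
  unexplained <- bands[!matches_full & !matches_frag]
  if (length(unexplained))
    return(list(genotype = NA_character_,
                diagnostic = paste("unexplained band(s):",
                                   paste(unexplained, collapse = ", "))))
  mand <- mandatory_fragments(frg)
  frag_ok <- all(vapply(mand, function(f) any(near(bands, f)), logical(1)))
  has_full <- any(matches_full)
  has_frag <- any(matches_frag & !matches_full)
  uncut <- setdiff(c(locus$allele1, locus$allele2), locus$cut_allele)
  geno <-
    if (has_full && !has_frag) paste0(uncut, uncut)
    else if (!has_full && has_frag && frag_ok)
      paste0(locus$cut_allele, locus$cut_allele)
    else if (has_full && has_frag && frag_ok)
      paste0(uncut, locus$cut_allele)
    else NA_character_
  if (is.na(geno))
    return(list(genotype = NA_character_,
                diagnostic = "pattern matches no genotype template (missing mandatory fragment?)"))
  list(genotype = canonical_genotype(geno), diagnostic = "ok")
}

#' Tabulate affected/unaffected genotype counts at one locus
#'
#' Counts each genotype among the affected and unaffected groups of a
#' cohort.  Dogs in the excluded group, and dogs with no call at this locus,
#' are omitted (a missing call excludes a dog from this locus's table only).
#'
#' @param cohort a `dcm_cohort`.
#' @param locus_name genotype column name.
#' @param assignment a [group_assignment] for the cohort.
#' @return A single-locus [count_table].
#' @export
tabulate_genotype_counts <- function(cohort, locus_name, assignment) {
  if (!locus_name %in% names(cohort))
    stop("locus not present in cohort: ", locus_name)
  calls <- canonical_genotype(cohort[[locus_name]])
  keep <- assignment$status %in% c("affected", "unaffected") & !is.na(calls)
  if (!any(keep)) stop("no classified, genotyped dogs at ", locus_name)
  calls <- calls[keep]
  aff <- assignment$status[keep] == "affected"
  genos <- sort(unique(calls))
  count_table(genos,
              affected = vapply(genos, function(g) sum(aff & calls == g),
                                numeric(1)),
              unaffected = vapply(genos, function(g) sum(!aff & calls == g),
                                  numeric(1)),
              loci = locus_name)
}

#' Allele frequencies at a locus
#'
#' Frequency of each allele among all called individuals (two observations
#' per individual), irrespective of disease status.
#'
#' @param x a single-locus [count_table] (affected + unaffected individuals
#'   per genotype) or a character vector of genotype calls (`NA` = not
#'   called).
#' @return Named numeric vector of frequencies summing to 1.
#' @examples
#' allele_frequencies(c("CC", "CT", "TT", "CC", NA))
#' @export
allele_frequencies <- function(x) {
  if (inherits(x, "count_table")) {
    stopifnot(length(ct_loci(x)) == 1L)
    counts <- allele_counts(ct_labels(x), x$affected + x$unaffected)
  } else {
    calls <- canonical_genotype(x)
    calls <- calls[!is.na(calls)]
    if (!length(calls)) stop("no genotype calls")
    counts <- allele_counts(calls, rep(1, length(calls)))
  }
  counts / sum(counts)
}
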