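#' Genotype count tables
#'
#' A `count_table` holds affected/unaffected counts per genotype class for
#' one locus or for a combination of two or three loci.  It is the unit all
#' association statistics and risk estimates consume: a `data.frame` with one
#' genotype-label column per locus, integer `affected` and `unaffected`
#' columns, and a `loci` attribute naming the loci in order.
#'
#' @param genotypes character vector (one locus) or data.frame/list of
#'   character vectors (multi-locus) of genotype labels, e.g. `"CT"` or the
#'   pooled label `"GA/GG"`.
#' @param affected,unaffected non-negative integer counts, one per row.
#' @param loci character vector of locus names, length 1--3.
#' @return An object of class `count_table`.
#' @examples
#' ct <- count_table(c("CC", "CT", "TT"), affected = c(44, 15, 2),
#'                   unaffected = c(10, 7, 2), loci = "Chr1")
#' genotype_risk(ct)
#' @export
count_table <- function(genotypes, affected, unaffected, loci) {
  if (is.character(genotypes)) genotypes <- list(genotypes)
  genotypes <- as.data.frame(genotypes, stringsAsFactors = FALSE,
                             optional = TRUE)
  if (missing(loci)) loci <- paste0("locus", seq_len(ncol(genotypes)))
  stopifnot(length(loci) == ncol(genotypes), length(loci) >= 1L,
            length(loci) <= 3L)
  names(genotypes) <- loci
  n <- nrow(genotypes)
  if (length(affected) != n || length(unaffected) != n)
    stop("counts must have one entry per genotype row")
  check_count <- function(x, what) {
    if (any(!is.finite(x)) || any(x < 0) || any(abs(x - round(x)) > 1e-8))
      stop(what, " counts must be non-negative integers")
    as.integer(round(x))
  }
  affected <- check_count(affected, "affected")
  unaffected <- check_count(unaffected, "unaffected")
  labels <- do.call(paste, c(genotypes, sep = ":"))
  if (anyDuplicated(labels))
    stop("duplicate genotype label: ", labels[duplicated(labels)][1L])
  if (sum(affected) + sum(unaffected) == 0L)
    stop("count table has zero total")
  out <- cbind(genotypes,
               data.frame(affected = affected, unaffected = unaffected))
  rownames(out) <- NULL
  structure(out, loci = loci, class = c("count_table", "data.frame"))
}

#' @export
print.count_table <- function(x, ...) {
  cat("Genotype count table (", paste(attr(x, "loci"), collapse = " x "),
      "): ", sum(x$affected), " affected / ", sum(x$unaffected),
      " unaffected\n", sep = "")
  print(as.data.frame(x), ...)
  invisible(x)
}

#' @rdname count_table
#' @param x a `count_table`.
#' @export
ct_loci <- function(x) attr(x, "loci")

#' Genotype labels of a count table, one string per row
#' @param x a `count_table`.
#' @return character vector, multi-locus labels joined with `" + "`.
#' @export
ct_labels <- function(x) {
  do.call(paste, c(as.list(as.data.frame(x)[ct_loci(x)]), sep = " + "))
}

#' Read a genotype count table from CSV
#'
#' Expected columns: one genotype-label column per locus (the locus names),
#' then `affected` and `unaffected`.  The locus list is inferred from the
#' header.
#'
#' @param path path to a CSV file.
#' @return A [count_table].
#' @export
read_count_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  need <- c("affected", "unaffected")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("count table missing column(s): ", paste(miss, collapse = ", "))
  loci <- setdiff(names(df), need)
  if (length(loci) < 1L || length(loci) > 3L)
    stop("expected 1-3 genotype columns, found ", length(loci))
  to_int <- function(x, what) {
    v <- suppressWarnings(as.numeric(x))
    if (any(is.na(v)) || any(abs(v - round(v)) > 1e-8))
      stop("non-integer ", what, " count in ", path)
    v
  }
  count_table(df[loci],
              affected = to_int(df$affected, "affected"),
              unaffected = to_int(df$unaffected, "unaffected"),
              loci = loci)
}

#' @rdname read_count_table
#' @param x a `count_table` to write.
#' @export
write_count_table <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
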