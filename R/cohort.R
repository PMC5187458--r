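#' @keywords internal
"_PACKAGE"

# Canonicalise genotype calls: alphabetical allele order ("TC" -> "CT").
# Pooled class labels (containing "/") and missing values pass through.
canonical_genotype <- function(x) {
  x <- trimws(as.character(x))
  x[x == ""] <- NA_character_
  plain <- !is.na(x) & nchar(x) == 2L & !grepl("/", x, fixed = TRUE)
  x[plain] <- vapply(strsplit(x[plain], "", fixed = TRUE),
                     function(a) paste(sort(a, method = "radix"), collapse = ""),
                     character(1))
  x
}

mandatory_cohort_cols <- c("dog_id", "sex", "neutered", "death_age_years",
                           "death_cause", "heart_tests")
optional_cohort_cols <- c("birth_known", "last_known_age_years")

parse_heart_tests <- function(s) {
  # "age:dcm:af;age:dcm:af" -> data.frame(age, dcm, af), sorted by age
  s <- trimws(s)
  if (is.na(s) || s == "")
    return(data.frame(age = numeric(0), dcm = logical(0), af = logical(0)))
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  if (any(lengths(parts) != 3L)) stop("malformed heart_tests entry")
  m <- do.call(rbind, parts)
  age <- suppressWarnings(as.numeric(m[, 1]))
  if (anyNA(age)) stop("unparseable heart-test age")
  df <- data.frame(age = age, dcm = m[, 2] == "1", af = m[, 3] == "1")
  df[order(df$age), , drop = FALSE]
}

encode_heart_tests <- function(df) {
  if (!nrow(df)) return("")
  paste(sprintf("%s:%d:%d",
                format(df$age, digits = 15, scientific = FALSE, trim = TRUE),
                as.integer(df$dcm), as.integer(df$af)),
        collapse = ";")
}

normalize_sex <- function(x) {
  x <- tolower(trimws(x))
  out <- ifelse(x %in% c("m", "male"), "male",
                ifelse(x %in% c("f", "female"), "female", NA_character_))
  out
}

#' Read a cohort CSV of dog records
#'
#' The cohort file has one row per dog with columns `dog_id`, `sex`
#' (male/female, normalised), `neutered` (yes/no/unknown), `death_age_years`
#' (blank if alive/unknown), `death_cause` (dcm_af/other/unknown/alive),
#' `heart_tests` (semicolon-separated `age:dcm:af` triplets, flags 0/1,
#' e.g. `"3.0:0:0;4.5:1:1"`), optionally `birth_known` (default TRUE) and
#' `last_known_age_years` (age at last contact; defaults to the latest
#' observed age), and then one column per genotyped locus (e.g.
#' `Chr1 = "CT"`; blank = not genotyped).  Genotype calls are canonicalised
#' to alphabetical allele order.
#'
#' Validated invariants per dog: heart-test ages finite, in \[0, 25\],
#' sorted (sorting is applied); death age, when present, at least the latest
#' heart-test age.  Violations are collected and reported as one error
#' listing the offending `dog_id`s (or attached as the `"problems"`
#' attribute when `strict = FALSE`).
#'
#' @param path path to the cohort CSV.
#' @param strict error on invariant violations (default) instead of
#'   collecting them.
#' @return A `dcm_cohort` data.frame; `heart_tests` is a list-column of
#'   per-dog data.frames `(age, dcm, af)`; attribute `"loci"` names the
#'   genotype columns.
#' @export
read_cohort <- function(path, strict = TRUE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  miss <- setdiff(mandatory_cohort_cols, names(df))
  if (length(miss))
    stop("cohort file missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  loci <- setdiff(names(df), c(mandatory_cohort_cols, optional_cohort_cols))
  problems <- list()
  note <- function(id, msg) problems[[length(problems) + 1L]] <<-
    data.frame(dog_id = id, problem = msg)

  num_or_na <- function(x) {
    x <- trimws(x)
    v <- suppressWarnings(as.numeric(x))
    v[x == ""] <- NA
    bad <- x != "" & is.na(v)
    list(value = v, bad = bad)
  }
  death <- num_or_na(df$death_age_years)
  for (i in which(death$bad)) note(df$dog_id[i], "unparseable death_age_years")

  tests <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    ht <- tryCatch(parse_heart_tests(df$heart_tests[i]), error = function(e) e)
    if (inherits(ht, "error")) {
      note(df$dog_id[i], conditionMessage(ht))
      ht <- data.frame(age = numeric(0), dcm = logical(0), af = logical(0))
    } else {
      if (any(!is.finite(ht$age) | ht$age < 0 | ht$age > 25))
        note(df$dog_id[i], "heart-test age outside [0, 25]")
      if (nrow(ht) && !is.na(death$value[i]) &&
          death$value[i] < max(ht$age) - 1e-9)
        note(df$dog_id[i], "death age earlier than latest heart test")
    }
    tests[[i]] <- ht
  }
  sex <- normalize_sex(df$sex)
  for (i in which(is.na(sex))) note(df$dog_id[i], "unrecognised sex")
  neutered <- tolower(trimws(df$neutered))
  neutered[!neutered %in% c("yes", "no")] <- "unknown"
  cause <- tolower(trimws(df$death_cause))
  cause[cause == ""] <- "alive"
  bad_cause <- !cause %in% c("dcm_af", "other", "unknown", "alive")
  for (i in which(bad_cause)) note(df$dog_id[i], "unrecognised death_cause")

  birth_known <- if ("birth_known" %in% names(df))
    !tolower(trimws(df$birth_known)) %in% c("false", "no", "0")
  else rep(TRUE, nrow(df))
  last_age <- if ("last_known_age_years" %in% names(df))
    num_or_na(df$last_known_age_years)$value else rep(NA_real_, nrow(df))
  obs_age <- vapply(seq_len(nrow(df)), function(i)
    suppressWarnings(max(c(tests[[i]]$age, death$value[i]), na.rm = TRUE)),
    numeric(1))
  obs_age[!is.finite(obs_age)] <- NA
  last_age <- ifelse(is.na(last_age), obs_age, pmax(last_age, obs_age, na.rm = TRUE))

  out <- data.frame(dog_id = df$dog_id, sex = sex, neutered = neutered,
                    birth_known = birth_known,
                    last_known_age_years = last_age,
                    death_age_years = death$value, death_cause = cause,
                    stringsAsFactors = FALSE)
  out$heart_tests <- tests
  for (l in loci) out[[l]] <- canonical_genotype(df[[l]])
  problems <- if (length(problems)) do.call(rbind, problems) else
    data.frame(dog_id = character(0), problem = character(0))
  if (strict && nrow(problems))
    stop("invalid cohort rows:\n",
         paste(sprintf("  %s: %s", problems$dog_id, problems$problem),
               collapse = "\n"))
  structure(out, loci = loci, problems = problems,
            class = c("dcm_cohort", "data.frame"))
}

#' @rdname read_cohort
#' @param cohort a `dcm_cohort`.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "dcm_cohort"))
  loci <- attr(cohort, "loci")
  fmt_num <- function(x) ifelse(is.na(x), "",
    format(x, digits = 15, scientific = FALSE, trim = TRUE))
  df <- data.frame(
    dog_id = cohort$dog_id, sex = cohort$sex, neutered = cohort$neutered,
    birth_known = ifelse(cohort$birth_known, "TRUE", "FALSE"),
    last_known_age_years = fmt_num(cohort$last_known_age_years),
    death_age_years = fmt_num(cohort$death_age_years),
    death_cause = cohort$death_cause,
    heart_tests = vapply(cohort$heart_tests, encode_heart_tests, character(1)),
    stringsAsFactors = FALSE, check.names = FALSE)
  for (l in loci) df[[l]] <- ifelse(is.na(cohort[[l]]), "", cohort[[l]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Locus names of a cohort
#' @param cohort a `dcm_cohort`.
#' @export
cohort_loci <- function(cohort) attr(cohort, "loci")

# Per-dog derived ages: first DCM / first AF diagnosis age, last test age.
cohort_ages <- function(cohort) {
  first_age <- function(ht, col)
    if (any(ht[[col]])) min(ht$age[ht[[col]]]) else NA_real_
  data.frame(
    dog_id = cohort$dog_id,
    first_dcm_age = vapply(cohort$heart_tests, first_age, numeric(1), "dcm"),
    first_af_age = vapply(cohort$heart_tests, first_age, numeric(1), "af"),
    last_test_age = vapply(cohort$heart_tests, function(ht)
      if (nrow(ht)) max(ht$age) else NA_real_, numeric(1)),
    n_tests = vapply(cohort$heart_tests, nrow, integer(1)),
    stringsAsFactors = FALSE)
}

#' @export
print.dcm_cohort <- function(x, ...) {
  ages <- cohort_ages(x)
  cat(sprintf("DCM/AF cohort: %d dogs (%d DCM, %d AF), loci: %s\n",
              nrow(x), sum(!is.na(ages$first_dcm_age)),
              sum(!is.na(ages$first_af_age)),
              paste(attr(x, "loci"), collapse = ", ")))
  invisible(x)
}
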