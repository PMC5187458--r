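#' Genotype penetrances under the four single-locus models
#'
#' Penetrance vector `(f_aa, f_Aa, f_AA)` over the genotype ordered by copies
#' of the risk allele, where `f0` is the disease risk of the least risky
#' homozygote (a/a) and `gamma` the penetrance parameter:
#' multiplicative `(f0, f0*g, f0*g^2)`, additive `(f0, f0*g, 2*f0*g)`,
#' recessive `(f0, f0, f0*g)`, dominant `(f0, f0*g, f0*g)`.  Each component
#' is capped at 1 (the additive heterozygote doubling can exceed it).
#'
#' @param kind one of `"multiplicative"`, `"additive"`, `"recessive"`,
#'   `"dominant"`.
#' @param f0 baseline risk in (0, 1].
#' @param gamma penetrance parameter, non-negative.
#' @return Numeric vector `c(aa = , Aa = , AA = )`.
#' @examples
#' penetrance_vector("multiplicative", 0.2, 2)  # 0.2 0.4 0.8
#' @export
penetrance_vector <- function(kind = c("multiplicative", "additive",
                                       "recessive", "dominant"),
                              f0, gamma) {
  kind <- match.arg(kind)
  stopifnot(f0 > 0, f0 <= 1, gamma >= 0)
  v <- switch(kind,
    multiplicative = c(f0, f0 * gamma, f0 * gamma^2),
    additive       = c(f0, f0 * gamma, 2 * f0 * gamma),
    recessive      = c(f0, f0, f0 * gamma),
    dominant       = c(f0, f0 * gamma, f0 * gamma))
  stats::setNames(pmin(v, 1), c("aa", "Aa", "AA"))
}

# Orient a single-locus 3-class table: a/a is the homozygote with the lower
# observed risk (ties broken by alphabetical allele order).  Returns row
# indices in (aa, het, AA) order plus the allele labels.
orient_table <- function(table) {
  labels <- ct_labels(table)
  het <- which(is_het(labels))
  hom <- which(!is_het(labels))
  if (length(het) > 1L || length(hom) != 2L)
    stop("penetrance fit needs a single-locus table with two homozygote ",
         "classes and at most one heterozygote class")
  total <- table$affected + table$unaffected
  risk <- ifelse(total > 0, table$affected / total, NA_real_)
  r <- risk[hom]
  aa <- if (anyNA(r) || isTRUE(all.equal(r[1], r[2]))) hom[order(labels[hom])][1]
        else hom[which.min(r)]
  AA <- setdiff(hom, aa)
  list(order = c(aa, het, AA),
       low_allele = substr(labels[aa], 1, 1),
       risk_allele = substr(labels[AA], 1, 1))
}

#' Fit a penetrance model to a single-locus genotype count table
#'
#' Estimates `(f0, gamma)` for one of the four penetrance models by
#' minimising the Pearson chi-square between observed and expected affected
#' counts, where the expected count of a genotype class is its penetrance
#' times the class total.  Orientation is fixed first: a/a is the homozygote
#' with the lower observed risk.  Classes with zero total are excluded from
#' the fit.  Minimisation is a vectorised coarse grid over
#' `f0 in (0,1] x gamma in [0.1, 10]` followed by box-constrained
#' quasi-Newton refinement; the procedure is deterministic and recovers
#' chi-square ~ 0 on tables lying exactly on a model surface.
#'
#' @param table a single-locus [count_table] with >= 2 non-empty classes.
#' @param kind penetrance model kind, see [penetrance_vector].
#' @return An object of class `penetrance_fit`: list with `kind`, `f0`,
#'   `gamma`, `chi2`, `orientation` (labels in `(aa, het, AA)` order),
#'   `risk_allele`, `observed`, `expected`, `totals`, `table`.
#' @examples
#' fit_penetrance(iwh_count_tables()$chr37, "recessive")
#' @export
fit_penetrance <- function(table, kind = c("multiplicative", "additive",
                                           "recessive", "dominant")) {
  kind <- match.arg(kind)
  stopifnot(inherits(table, "count_table"))
  ori <- orient_table(table)
  idx <- ori$order
  labels <- ct_labels(table)[idx]
  obs <- table$affected[idx]
  tot <- (table$affected + table$unaffected)[idx]
  use <- tot > 0
  if (sum(use) < 2L) stop("fewer than 2 non-empty genotype classes: unfittable")

  objective <- function(f0, gamma) {
    # vectorised over equal-length f0/gamma
    f <- switch(kind,
      multiplicative = cbind(f0, f0 * gamma, f0 * gamma^2),
      additive       = cbind(f0, f0 * gamma, 2 * f0 * gamma),
      recessive      = cbind(f0, f0, f0 * gamma),
      dominant       = cbind(f0, f0 * gamma, f0 * gamma))
    f <- pmin(f, 1)
    e <- sweep(f[, use, drop = FALSE], 2L, tot[use], `*`)
    o <- matrix(obs[use], nrow(e), ncol(e), byrow = TRUE)
    rowSums((o - e)^2 / e)
  }
  g0 <- expand.grid(f0 = seq(0.01, 1, by = 0.01),
                    gamma = seq(0.1, 10, by = 0.05))
  val <- objective(g0$f0, g0$gamma)
  best <- which.min(val)
  opt <- stats::optim(c(g0$f0[best], g0$gamma[best]),
                      function(p) objective(p[1], p[2]),
                      method = "L-BFGS-B",
                      lower = c(1e-4, 0.1), upper = c(1, 10))
  f0 <- opt$par[1]; gamma <- opt$par[2]
  pen <- penetrance_vector(kind, f0, gamma)
  structure(list(kind = kind, f0 = f0, gamma = gamma, chi2 = opt$value,
                 orientation = labels, risk_allele = ori$risk_allele,
                 low_allele = ori$low_allele,
                 observed = obs, expected = unname(pen * tot), totals = tot,
                 table = table),
            class = "penetrance_fit")
}

#' Select the best-fitting penetrance model for a locus
#'
#' Fits all four penetrance models ([fit_penetrance]) and selects the one
#' with the smallest minimised chi-square; ties are broken in the fixed
#' order multiplicative, additive, dominant, recessive.  The winning model
#' determines the association test type: multiplicative maps to the allelic
#' test, additive to the Cochran-Armitage trend test, dominant/recessive to
#' the corresponding pooled two-class tests.
#'
#' @param table a single-locus [count_table].
#' @return An object of class `penetrance_selection`: list with `kind`
#'   (winner), `test_type`, `fits` (all four `penetrance_fit`s),
#'   `risk_allele`, `chi2` (named vector of all four).
#' @examples
#' select_penetrance_model(iwh_count_tables()$chr21)  # dominant, risk allele G
#' @export
select_penetrance_model <- function(table) {
  kinds <- c("multiplicative", "additive", "dominant", "recessive")
  fits <- lapply(kinds, function(k) fit_penetrance(table, k))
  names(fits) <- kinds
  chi2 <- vapply(fits, `[[`, numeric(1), "chi2")
  # which.min on this ordering implements the documented tie-break
  winner <- kinds[which.min(chi2)]
  test_type <- c(multiplicative = "allelic", additive = "trend",
                 dominant = "pooled_dominant",
                 recessive = "pooled_recessive")[[winner]]
  structure(list(kind = winner, test_type = test_type, fits = fits,
                 risk_allele = fits[[winner]]$risk_allele, chi2 = chi2),
            class = "penetrance_selection")
}

#' @export
print.penetrance_fit <- function(x, ...) {
  cat(sprintf("%s penetrance model: f0 = %.3f, gamma = %.3f, chi2 = %.4g\n",
              x$kind, x$f0, x$gamma, x$chi2))
  cat("  orientation (aa, Aa, AA):", paste(x$orientation, collapse = ", "),
      "| risk allele:", x$risk_allele, "\n")
  invisible(x)
}

#' @export
coef.penetrance_fit <- function(object, ...) {
  c(f0 = object$f0, gamma = object$gamma)
}

#' @export
summary.penetrance_fit <- function(object, ...) {
  out <- data.frame(genotype = object$orientation,
                    total = object$totals,
                    observed_affected = object$observed,
                    expected_affected = object$expected,
                    penetrance = unname(
                      penetrance_vector(object$kind, object$f0, object$gamma)))
  structure(list(fit = object, table = out), class = "summary.penetrance_fit")
}

#' @export
print.summary.penetrance_fit <- function(x, ...) {
  print(x$fit)
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Predicted penetrance per genotype class
#'
#' @param object a `penetrance_fit`.
#' @param newdata optional character vector of genotype labels (defaults to
#'   the fitted table's labels in orientation order).
#' @param ... unused.
#' @return Named numeric penetrances.
#' @export
predict.penetrance_fit <- function(object, newdata = NULL, ...) {
  pen <- penetrance_vector(object$kind, object$f0, object$gamma)
  lev <- stats::setNames(pen, object$orientation)
  if (is.null(newdata)) return(lev)
  canon <- canonical_genotype(newdata)
  lev[match(canon, canonical_genotype(object$orientation))]
}

#' @export
residuals.penetrance_fit <- function(object, type = c("pearson", "response"),
                                     ...) {
  type <- match.arg(type)
  r <- object$observed - object$expected
  if (type == "pearson") r <- r / sqrt(pmax(object$expected, .Machine$double.eps))
  stats::setNames(r, object$orientation)
}

#' Simulate replicate count tables from a fitted penetrance model
#'
#' Parametric-bootstrap style replicates: affected counts per genotype class
#' are redrawn as binomials at the fitted penetrances with the observed
#' class totals.
#'
#' @param object a `penetrance_fit`.
#' @param nsim number of replicate tables.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return List of [count_table]s of length `nsim`.
#' @export
simulate.penetrance_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  pen <- unname(penetrance_vector(object$kind, object$f0, object$gamma))
  lapply(seq_len(nsim), function(i) {
    aff <- stats::rbinom(length(object$totals), object$totals, pen)
    count_table(object$orientation, affected = aff,
                unaffected = object$totals - aff,
                loci = ct_loci(object$table))
  })
}

#' @export
print.penetrance_selection <- function(x, ...) {
  cat("Penetrance model selection (smallest chi-square wins):\n")
  print(round(x$chi2, 4))
  cat(sprintf("Winner: %s (risk allele %s) -> %s test\n",
              x$kind, x$risk_allele, x$test_type))
  invisible(x)
}
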