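# Build a cohort CSV in a temp file from header + row strings.
cohort_csv <- function(rows,
                       header = "dog_id,sex,neutered,death_age_years,death_cause,heart_tests,Chr1,Chr21") {
  path <- tempfile(fileext = ".csv")
  writeLines(c(header, rows), path)
  path
}

# Pooled-variance two-sample t statistic, written out as the textbook
# formula so it can serve as an independent oracle for t.test-based code.
pooled_t_oracle <- function(x, y) {
  sp2 <- ((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
    (length(x) + length(y) - 2)
  (mean(x) - mean(y)) / sqrt(sp2 * (1 / length(x) + 1 / length(y)))
}

# Brute-force Pearson goodness-of-fit sum, skipping zero-expected cells.
brute_chi2 <- function(o, e) {
  s <- 0
  for (i in seq_along(o)) if (e[i] > 0) s <- s + (o[i] - e[i])^2 / e[i]
  s
}

# Exhaustive grid-search penetrance oracle: minimum chi-square for one model
# kind over a fine (f0, gamma) grid, independent of the package's optimiser.
grid_fit_oracle <- function(obs, tot, kind,
                            f0s = seq(0.02, 1, by = 0.002),
                            gammas = seq(0.1, 10, by = 0.02)) {
  best <- Inf
  for (g in gammas) {
    pen3 <- switch(kind,
      multiplicative = rbind(f0s, f0s * g, f0s * g^2),
      additive       = rbind(f0s, f0s * g, 2 * f0s * g),
      recessive      = rbind(f0s, f0s, f0s * g),
      dominant       = rbind(f0s, f0s * g, f0s * g))
    pen3 <- pmin(pen3, 1)
    e <- pen3 * tot
    use <- tot > 0
    chi <- colSums((obs[use] - e[use, , drop = FALSE])^2 / e[use, , drop = FALSE])
    best <- min(best, min(chi))
  }
  best
}

# single simulated locus used across tests
null_locus <- function(freq = 0.4, f0 = 0.3)
  sim_locus("L1", c("A", "a"), "A", freq, "multiplicative", f0, 1)
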