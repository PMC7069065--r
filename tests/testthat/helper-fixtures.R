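# Fixtures and independent brute-force oracles used across the suite.
# Oracles deliberately avoid the code paths they check (no stats::cor, no
# package internals).

fixture_table_4x5 <- function() {
  tibble::tibble(
    region = c("rA", "rB", "rC", "rD"),
    f1 = c(1.3, -0.7, 2.2, 0.4),
    f2 = c(0.5, 1.9, -1.1, 0.8),
    f3 = c(-2.0, 0.3, 1.4, -0.6),
    f4 = c(0.9, -1.2, 0.1, 2.5),
    f5 = c(1.1, 0.6, -0.9, -1.7)
  )
}

# Pearson r via the raw-sum covariance formula
oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

# column z-scores via explicit mean / sample-SD sums
oracle_zscore <- function(m) {
  out <- apply(m, 2L, function(col) {
    mu <- sum(col) / length(col)
    s <- sqrt(sum((col - mu)^2) / (length(col) - 1))
    (col - mu) / s
  })
  rownames(out) <- rownames(m)
  out
}

# build a symmetric zero-diagonal matrix from 10 lower-triangle values
sym5 <- function(vals, labels = paste0("n", 1:5)) {
  stopifnot(length(vals) == 10)
  w <- matrix(0, 5, 5, dimnames = list(labels, labels))
  w[lower.tri(w)] <- vals
  w + t(w)
}

fixture_sym5_a <- function() {
  sym5(c(0.62, -0.41, 0.17, 0.88, -0.23, 0.05, 0.71, -0.64, 0.33, -0.12))
}

fixture_sym5_b <- function() {
  sym5(c(0.55, -0.30, 0.20, 0.79, -0.35, 0.11, 0.60, -0.50, 0.41, -0.05))
}

# independent permutation enumerator (recursion over the first element;
# different algorithm from the package's insertion-based one)
oracle_perms <- function(v) {
  if (length(v) == 1L) return(list(v))
  unlist(lapply(seq_along(v), function(i) {
    lapply(oracle_perms(v[-i]), function(p) c(v[i], p))
  }), recursive = FALSE)
}

tiny_cohort <- function(n_subjects = 10, seed = 1, n_regions = 68, ...) {
  generate_cohort(cohort_config(n_subjects = n_subjects, seed = seed,
                                n_regions = n_regions, ...))
}
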