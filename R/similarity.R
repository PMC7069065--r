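# Pairwise network-similarity statistics: edge-weight Pearson (all / mutually
# nonzero), Mantel matrix correlation, binary edge replication, paired-t
# effect sizes.

.check_same_shape <- function(X, Y) {
  if (!all(dim(X) == dim(Y))) stop("matrices differ in dimension", call. = FALSE)
  rx <- rownames(X); ry <- rownames(Y)
  if (!is.null(rx) && !is.null(ry) && !identical(rx, ry)) {
    stop("matrices have different region order", call. = FALSE)
  }
}

.offdiag <- function(X) X[row(X) != col(X)]

#' Pearson correlation of edge weights between two networks
#'
#' Correlates the edge weights of two node-aligned networks. `mode = "all"`
#' uses every off-diagonal element (the diagonal is always excluded);
#' `mode = "nonzero"` restricts to elements that are nonzero in *both*
#' matrices, i.e. edges surviving thresholding in both networks — elements
#' zeroed in either network are excluded.
#'
#' @param X,Y Weighted matrices (`thresholded_msn`, `msn_matrix` or plain
#'   symmetric matrices) with identical dimension and region order.
#' @param mode `"all"` or `"nonzero"`.
#' @return Pearson r.
#' @export
edge_correlation <- function(X, Y, mode = c("all", "nonzero")) {
  mode <- match.arg(mode)
  X <- .net_weights(X); Y <- .net_weights(Y)
  .check_same_shape(X, Y)
  x <- .offdiag(X); y <- .offdiag(Y)
  if (mode == "nonzero") {
    keep <- x != 0 & y != 0
    x <- x[keep]; y <- y[keep]
  }
  if (length(x) < 3L) {
    stop("fewer than 3 usable element pairs; correlation undefined",
         call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in edge weights; correlation undefined", call. = FALSE)
  }
  stats::cor(x, y)
}

.lower_tri <- function(X) X[lower.tri(X)]

#' Mantel matrix correlation
#'
#' Pearson correlation between the half-vectorized off-diagonals (strictly
#' lower triangles) of two symmetric matrices. Because a symmetric matrix
#' duplicates each off-diagonal element, this equals
#' `edge_correlation(mode = "all")` when the diagonal is excluded; it is kept
#' as a distinct statistic because the duplication argument is not obvious
#' and the half-matrix form admits a permutation test.
#'
#' With `n_perm > 0` a permutation p-value is computed by simultaneously
#' permuting the rows and columns of `Y`: two-sided, with +1 smoothing,
#' p = (1 + #\{|r_perm| >= |r_obs|\}) / (n_perm + 1). With
#' `exhaustive = TRUE` all n! node permutations are enumerated (small n only)
#' and p is the exact proportion with |r_perm| >= |r_obs|.
#'
#' @param X,Y Symmetric matrices (or `thresholded_msn`) of equal dimension.
#' @param n_perm Number of random permutations (0 = no test, the default:
#'   the statistic is used descriptively).
#' @param seed Integer seed for the permutations.
#' @param exhaustive Enumerate all node permutations instead (requires
#'   n <= 8).
#' @return A list with `r` and (when a test is run) `p` and `n_perm`.
#' @export
mantel_statistic <- function(X, Y, n_perm = 0, seed = NULL,
                             exhaustive = FALSE) {
  X <- .net_weights(X); Y <- .net_weights(Y)
  .check_same_shape(X, Y)
  if (!isSymmetric(unname(X), tol = 1e-10) ||
      !isSymmetric(unname(Y), tol = 1e-10)) {
    stop("mantel_statistic requires symmetric matrices", call. = FALSE)
  }
  x <- .lower_tri(X)
  r_obs <- stats::cor(x, .lower_tri(Y))
  if (!exhaustive && n_perm <= 0) return(list(r = r_obs))

  n <- nrow(X)
  perm_r <- function(p) stats::cor(x, .lower_tri(Y[p, p]))
  if (exhaustive) {
    if (n > 8L) stop("exhaustive enumeration limited to n <= 8", call. = FALSE)
    perms <- .all_permutations(n)
    rs <- vapply(perms, perm_r, numeric(1))
    p_val <- mean(abs(rs) >= abs(r_obs) - 1e-12)
    return(list(r = r_obs, p = p_val, n_perm = length(perms)))
  }
  rs <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(b) perm_r(sample.int(n)), numeric(1))
  })
  p_val <- (1 + sum(abs(rs) >= abs(r_obs) - 1e-12)) / (n_perm + 1)
  list(r = r_obs, p = p_val, n_perm = n_perm)
}

.all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- .all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (p in sub) {
    for (pos in 0:(n - 1L)) {
      k <- k + 1L
      out[[k]] <- append(p, n, after = pos)
    }
  }
  out
}

#' Binary edge replication proportion
#'
#' The fraction of the reference (fuller) network's suprathreshold edges that
#' are also suprathreshold in a second network:
#' sum(x != 0 & y != 0) / sum(x != 0) over off-diagonal elements, where x is
#' the reference. When both networks are thresholded at the same density
#' (equal edge counts) the statistic is symmetric in its arguments.
#'
#' @param X_binary Reference (fuller model) binary network: 0/1 symmetric
#'   matrix or `thresholded_msn`.
#' @param Y_binary Comparison (reduced model) binary network.
#' @return Proportion in \[0, 1\].
#' @export
replication_proportion <- function(X_binary, Y_binary) {
  bx <- if (inherits(X_binary, "thresholded_msn")) X_binary$binary else X_binary
  by <- if (inherits(Y_binary, "thresholded_msn")) Y_binary$binary else Y_binary
  .check_same_shape(bx, by)
  x <- .offdiag(bx) != 0
  y <- .offdiag(by) != 0
  if (!any(x)) stop("reference network has no edges", call. = FALSE)
  sum(x & y) / sum(x)
}

#' Paired-t effect size between two per-subject metric distributions
#'
#' Paired t test on subject-matched metric vectors, reported as the effect
#' size r = sqrt(t^2 / (t^2 + df)) rather than a p-value (the standard
#' conversion for a paired t with df = n - 1; with many density-by-contrast
#' comparisons, effect sizes are the informative summary).
#'
#' @param a,b Numeric vectors of equal length >= 3, paired by subject.
#' @param label Optional contrast label carried into the output.
#' @return A one-row tibble: `contrast`, `t`, `df`, `r_effect`.
#' @export
paired_effect_size <- function(a, b, label = NA_character_) {
  stopifnot(length(a) == length(b))
  if (length(a) < 3L) stop("need at least 3 pairs", call. = FALSE)
  d <- a - b
  if (stats::sd(d) == 0) {
    stop("zero variance of paired differences; t undefined", call. = FALSE)
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  t_stat <- unname(tt$statistic)
  df <- unname(tt$parameter)
  tibble::tibble(
    contrast = label, t = t_stat, df = df,
    r_effect = sqrt(t_stat^2 / (t_stat^2 + df))
  )
}

#' All similarity statistics for one network pair
#'
#' Convenience wrapper computing the full record the reliability analyses
#' emit for a pair of thresholded networks: all-edge Pearson, mutually
#' nonzero Pearson, Mantel r and the binary replication proportion (X as the
#' reference model).
#'
#' @param X,Y `thresholded_msn` objects at the same density.
#' @return A one-row tibble: `r_all`, `r_nonzero`, `mantel_r`,
#'   `prop_replicated`.
#' @export
similarity_record <- function(X, Y) {
  tibble::tibble(
    r_all = edge_correlation(X, Y, mode = "all"),
    r_nonzero = tryCatch(edge_correlation(X, Y, mode = "nonzero"),
                         error = function(e) NA_real_),
    mantel_r = mantel_statistic(X, Y)$r,
    prop_replicated = replication_proportion(X, Y)
  )
}
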