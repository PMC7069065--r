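# MSN construction: feature z-scoring, region-pair correlation, proportional
# density thresholding, strength metrics.

.ft_matrix <- function(table) {
  num <- vapply(table, is.numeric, logical(1))
  m <- as.matrix(table[num])
  rownames(m) <- table$region
  m
}

#' Z-score morphometric features across regions
#'
#' Each feature column is demeaned and scaled to unit sample SD across the
#' regions, neutralizing the order-of-magnitude scale differences between raw
#' morphometrics (gray-matter volume is of order 10^3 mm^3, mean diffusivity
#' of order 10^-3 mm^2/s) so that region-pair correlations weight every
#' feature equally.
#'
#' @param table A `feature_table` tibble (`region` column plus numeric
#'   feature columns).
#' @return A tibble of the same shape with each feature column standardized
#'   (mean 0, sample SD 1 across regions).
#' @export
zscore_features <- function(table) {
  m <- .ft_matrix(table)
  sds <- apply(m, 2L, stats::sd)
  if (any(sds == 0 | !is.finite(sds))) {
    stop("zero-variance feature(s): ",
         paste(colnames(m)[sds == 0 | !is.finite(sds)], collapse = ", "),
         call. = FALSE)
  }
  z <- sweep(sweep(m, 2L, colMeans(m)), 2L, sds, "/")
  out <- tibble::as_tibble(z)
  tibble::add_column(out, region = table$region, .before = 1L)
}

#' Build a morphometric similarity network
#'
#' Constructs the per-subject MSN: after z-scoring features across regions,
#' edge (i, j) is the Pearson correlation between region i's and region j's
#' feature vectors. The diagonal (self-similarity) is set to 0. Because each
#' feature is zero-centered across regions, the off-diagonal weights are
#' approximately normally distributed about zero.
#'
#' @param table A `feature_table` tibble.
#' @param zscore Standardize features across regions first (default `TRUE`;
#'   set `FALSE` only if `table` is already standardized).
#' @return An `msn_matrix`: a symmetric n x n numeric matrix of Pearson r
#'   with zero diagonal and region labels as dimnames.
#' @export
build_msn <- function(table, zscore = TRUE) {
  if (zscore) table <- zscore_features(table)
  m <- .ft_matrix(table)
  if (ncol(m) < 3L) {
    stop("at least 3 features are required (Pearson r of length-2 vectors ",
         "is degenerate)", call. = FALSE)
  }
  row_sd <- apply(m, 1L, stats::sd)
  if (any(row_sd == 0)) {
    stop("zero-variance feature vector for region(s): ",
         paste(rownames(m)[row_sd == 0], collapse = ", "), call. = FALSE)
  }
  w <- stats::cor(t(m))
  diag(w) <- 0
  structure(w, class = c("msn_matrix", class(w)))
}

# Off-diagonal undirected edge list (i < j), ordered by descending signed
# weight, ties broken by ascending (i, j). The deterministic total order makes
# retained edge sets nest monotonically across densities.
.edge_order <- function(w) {
  n <- nrow(w)
  ij <- which(upper.tri(w), arr.ind = TRUE)  # i < j (row < col)
  val <- w[ij]
  ord <- order(-val, ij[, 1L], ij[, 2L])
  list(i = ij[ord, 1L], j = ij[ord, 2L], w = val[ord])
}

.round_half_up <- function(x) floor(x + 0.5)

#' Proportional density thresholding
#'
#' Retains the k = round(d * n(n-1)/2) strongest off-diagonal edges of a
#' weighted network and zeroes the rest, so that networks compared at the
#' same density d always have the same edge count. Ranking is by signed
#' weight (most positive first) by default; ties at the cutoff are broken by
#' ascending (i, j) edge index, which makes the retained edge sets nest
#' monotonically in d. `rank_by = "absolute"` ranks by |weight| instead, for
#' sensitivity analysis.
#'
#' @param msn An `msn_matrix` (or any symmetric zero-diagonal matrix).
#' @param d Target edge density in (0, 1].
#' @param rank_by `"signed"` (default) or `"absolute"`.
#' @return A `thresholded_msn`: list with `weighted` (sub-threshold entries
#'   zeroed), `binary` (0/1 indicator), `density`, `k_edges` and `rank_by`.
#' @export
threshold_density <- function(msn, d, rank_by = c("signed", "absolute")) {
  rank_by <- match.arg(rank_by)
  if (!is.numeric(d) || length(d) != 1L || d <= 0 || d > 1) {
    stop("density d must be in (0, 1]", call. = FALSE)
  }
  w <- unclass(msn)
  n <- nrow(w)
  k <- .round_half_up(d * n * (n - 1) / 2)
  ranked <- if (rank_by == "signed") .edge_order(w) else {
    eo <- .edge_order(abs(w))
    eo
  }
  keep <- seq_len(k)
  weighted <- matrix(0, n, n, dimnames = dimnames(w))
  if (k > 0) {
    ik <- ranked$i[keep]; jk <- ranked$j[keep]
    weighted[cbind(ik, jk)] <- w[cbind(ik, jk)]
    weighted[cbind(jk, ik)] <- w[cbind(jk, ik)]
  }
  binary <- (weighted != 0) * 1L
  structure(
    list(weighted = weighted, binary = binary, density = d, k_edges = k,
         rank_by = rank_by),
    class = "thresholded_msn"
  )
}

#' @export
print.thresholded_msn <- function(x, ...) {
  cat(sprintf("<thresholded_msn> %d nodes, density %.2f (%d edges)\n",
              nrow(x$weighted), x$density, x$k_edges))
  invisible(x)
}

.net_weights <- function(net) {
  if (inherits(net, "thresholded_msn")) net$weighted else unclass(net)
}

#' Nodal strength
#'
#' Strength of node i is the sum of the weights of all edges incident to it.
#' The measure is deliberately not normalized by edge count: under equal
#' density thresholding all compared networks have the same number of edges,
#' so sums are directly comparable.
#'
#' @param net A `thresholded_msn`, `msn_matrix`, or symmetric matrix.
#' @return Named numeric vector of per-node strengths.
#' @export
nodal_strength <- function(net) {
  rowSums(.net_weights(net))
}

#' Graph strength
#'
#' Mean of the nodal strengths: the graph-level magnitude of morphometric
#' similarity.
#'
#' @inheritParams nodal_strength
#' @return A single number.
#' @export
graph_strength <- function(net) {
  mean(nodal_strength(net))
}

#' Write an MSN matrix as TSV
#'
#' @param w Square matrix (weighted or binary) with region dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_msn <- function(w, path) {
  w <- .net_weights(w)
  out <- data.frame(region = rownames(w), w, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
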