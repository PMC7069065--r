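# MSN construction, thresholding, strength metrics.

test_that("z-scoring gives each feature mean 0 and sample SD 1", {
  tbl <- fixture_table_4x5()
  z <- zscore_features(tbl)
  m <- as.matrix(z[-1])
  expect_true(all(abs(colMeans(m)) < 1e-12))
  expect_equal(unname(apply(m, 2, sd)), rep(1, 5))
  # closed form for (1, 2, 3) with sample SD
  t3 <- tibble::tibble(region = c("a", "b", "c"),
                       f1 = c(1, 2, 3), f2 = c(5, 1, 9), f3 = c(0, 2, 1))
  expect_equal(zscore_features(t3)$f1, c(-1, 0, 1))
  # constant feature errors by name
  t3$f2 <- 7
  expect_error(zscore_features(t3), "f2")
})

test_that("MSN edge weights match a brute-force Pearson oracle", {
  tbl <- fixture_table_4x5()
  msn <- build_msn(tbl)
  z <- oracle_zscore(as.matrix(tbl[-1]))
  for (i in 1:3) for (j in (i + 1):4) {
    expect_equal(msn[i, j], oracle_pearson(z[i, ], z[j, ]),
                 tolerance = 1e-12)
    expect_equal(msn[i, j], msn[j, i])
  }
  expect_true(all(diag(msn) == 0))
})

test_that("identical and anti-affine regions give edge weights 1 and -1", {
  # identical rows survive column z-scoring
  tbl <- fixture_table_4x5()
  tbl[2, -1] <- tbl[1, -1]
  msn <- build_msn(tbl)
  expect_equal(msn[1, 2], 1)
  # y = -x + c is exact anti-correlation (no z-scoring so rows are untouched)
  raw <- tibble::tibble(region = c("a", "b", "c"),
                        f1 = c(1, -1 + 5, 0.3),
                        f2 = c(2, -2 + 5, -0.4),
                        f3 = c(-1, 1 + 5, 1.2),
                        f4 = c(0.5, -0.5 + 5, 2.0))
  msn2 <- build_msn(raw, zscore = FALSE)
  expect_equal(msn2[1, 2], -1)
})

test_that("degenerate inputs to build_msn error informatively", {
  tbl <- fixture_table_4x5()[, 1:3]  # 2 features
  expect_error(build_msn(tbl, zscore = FALSE), "3 features")
  t2 <- fixture_table_4x5()
  t2[3, -1] <- as.list(rep(0.5, 5))
  expect_error(build_msn(t2, zscore = FALSE), "rC")
})

test_that("MSN is invariant to affine rescaling of raw features", {
  co <- tiny_cohort(2, seed = 11)
  tbl <- co$features[[1]]
  msn1 <- build_msn(tbl)
  tbl2 <- tbl
  tbl2$GM <- tbl2$GM * 1e6 + 300
  tbl2$MD <- tbl2$MD * 1e6 + 300
  msn2 <- build_msn(tbl2)
  expect_equal(unclass(msn1), unclass(msn2), tolerance = 1e-10)
})

test_that("edge weights are near-zero-centered on default cohorts", {
  co <- tiny_cohort(10, seed = 12)
  means <- vapply(co$features, function(ft) {
    m <- build_msn(ft)
    mean(m[row(m) != col(m)])
  }, numeric(1))
  expect_true(all(abs(means) < 0.05))
})

test_that("nested models agree whether built from subsets or subset files", {
  co <- tiny_cohort(2, seed = 13)
  tbl <- co$features[[1]]
  p <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(subset_features(tbl, "msn8"), p)
  from_file <- build_msn(read_feature_table(p, spec = feature_set("msn8")))
  from_subset <- build_msn(subset_features(tbl, "msn8"))
  expect_equal(unclass(from_file), unclass(from_subset), tolerance = 1e-12)
})

test_that("density thresholding retains exactly round(d * n(n-1)/2) edges", {
  co <- tiny_cohort(2, seed = 14)
  msn <- build_msn(co$features[[1]])
  thr <- threshold_density(msn, 0.40)
  expect_equal(thr$k_edges, 911)  # round(0.4 * 2278)
  expect_equal(sum(thr$binary) / 2, 911)
  expect_true(isSymmetric(thr$weighted))
  expect_true(all(diag(thr$weighted) == 0))
  # d = 1 is a no-op on the weights
  full <- threshold_density(msn, 1)
  expect_equal(full$weighted, unclass(msn))
  expect_true(all(full$binary[row(full$binary) != col(full$binary)] == 1))
  expect_error(threshold_density(msn, 0), "density")
  expect_error(threshold_density(msn, 1.1), "density")
})

test_that("retained edges match an exhaustive sort oracle and nest in d", {
  w <- fixture_sym5_a()
  # oracle: rank all 10 edges by signed weight, ties by (i, j)
  ij <- which(upper.tri(w), arr.ind = TRUE)
  ord <- order(-w[ij], ij[, 1], ij[, 2])
  prev_set <- integer(0)
  for (d in c(0.1, 0.3, 0.5, 0.8, 1)) {
    k <- floor(d * 10 + 0.5)
    keep_oracle <- sort(ord[seq_len(k)])
    thr <- threshold_density(w, d)
    keep_got <- sort(which(thr$weighted[ij] != 0))
    expect_equal(keep_got, keep_oracle)
    expect_true(all(prev_set %in% keep_got))  # monotone nesting
    prev_set <- keep_got
  }
})

test_that("ties at the cutoff break deterministically by edge index", {
  w <- sym5(rep(0.5, 10))
  thr <- threshold_density(w, 0.3)  # k = 3 of 10 equal weights
  ij <- which(upper.tri(w), arr.ind = TRUE)
  kept <- which(thr$weighted[ij] != 0)
  ord <- order(ij[, 1], ij[, 2])
  expect_equal(sort(kept), sort(ord[1:3]))
  expect_identical(threshold_density(w, 0.3)$weighted, thr$weighted)
})

test_that("strength metrics match closed forms and row-sum oracles", {
  n <- 6
  w <- matrix(0.3, n, n); diag(w) <- 0
  expect_equal(unname(nodal_strength(w)), rep((n - 1) * 0.3, n))
  expect_equal(graph_strength(w), (n - 1) * 0.3)
  wf <- fixture_sym5_a()
  oracle <- vapply(1:5, function(i) sum(wf[i, -i]), numeric(1))
  expect_equal(unname(nodal_strength(wf)), oracle)
  expect_equal(graph_strength(wf), mean(oracle))
  expect_equal(unname(nodal_strength(matrix(0, 4, 4))), rep(0, 4))
  expect_equal(graph_strength(matrix(0, 4, 4)), 0)
})
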