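# EF summary PCA, confound residualization, Q^2, PLS component selection,
# BCa bootstrap weights.

test_that("ef_summary of three identical columns returns the standardized column", {
  set.seed(71)
  x <- rnorm(50)
  out <- ef_summary(cbind(x, x, x))
  expect_equal(out$eigenvalue, 3)
  expect_equal(out$scores, as.numeric(scale(x)), tolerance = 1e-10)
  expect_true(all(out$loadings > 0))
})

test_that("ef_summary recovers the compound-symmetric eigenvalue 1 + 2 rho", {
  set.seed(72)
  n <- 4000
  g <- rnorm(n)
  lam <- sqrt(0.5)  # pairwise rho = 0.5, lambda1 = 2.0
  ef <- vapply(1:3, function(j) lam * g + sqrt(1 - lam^2) * rnorm(n),
               numeric(n))
  out <- ef_summary(ef)
  expect_lt(abs(out$eigenvalue - 2.0), 0.1)
  expect_equal(sd(out$scores), 1, tolerance = 1e-9)
})

test_that("ef_summary enforces its retention rules", {
  # exactly orthogonal centered columns: correlation identity, eigenvalue 1
  orth <- poly(1:20, 3)
  expect_error(ef_summary(unclass(orth)), "eigenvalue")
  # mixed-sign loadings
  set.seed(73)
  g <- rnorm(200)
  mixed <- cbind(g + rnorm(200, sd = 0.1), g + rnorm(200, sd = 0.1),
                 -g + rnorm(200, sd = 0.1))
  expect_error(ef_summary(mixed), "common sign")
  expect_error(ef_summary(cbind(g, g)), "3 EF")
  expect_error(ef_summary(cbind(g, g, rep(1, 200))), "zero-variance")
})

test_that("confound residualization removes age/sex structure", {
  set.seed(74)
  n <- 120
  age <- runif(n, 22, 36)
  sex <- sample(c("F", "M"), n, replace = TRUE)
  # metric exactly 2 * age: residuals vanish
  m <- matrix(2 * age, n, 4)
  res <- residualize_confounds(m, age, sex)
  expect_lt(max(abs(res)), 1e-10)
  # independent metric: residuals keep most variance, means ~ 0
  m2 <- matrix(rnorm(n * 6), n, 6)
  res2 <- residualize_confounds(m2, age, sex)
  expect_true(all(abs(colMeans(res2)) < 1e-10))
  r2 <- 1 - colSums(res2^2) / colSums(scale(m2, scale = FALSE)^2)
  expect_lt(max(r2), 0.12)
  # single-sex design collapses
  expect_error(residualize_confounds(m2, age, rep("F", n)), "rank")
})

test_that("q_squared matches its defining arithmetic", {
  y <- c(1, 2, 3, 4)
  expect_equal(q_squared(y, y), 1)
  expect_equal(q_squared(y, rep(mean(y), 4)), 0)
  expect_equal(q_squared(y, c(1, 2, 3, 0)), 1 - 16 / 5)  # = -2.2
  # exact zero for mean prediction is invariant to shifting y
  expect_identical(q_squared(y + 100, rep(mean(y + 100), 4)), 0)
  expect_error(q_squared(rep(2, 4), rep(2, 4)), "zero total")
})

test_that("PLS1 predictions agree with mixOmics", {
  skip_if_not_installed("mixOmics")
  set.seed(75)
  X <- matrix(rnorm(40 * 6), 40, 6)
  colnames(X) <- paste0("v", 1:6)
  y <- 2 * X[, 1] - X[, 3] + rnorm(40, sd = 0.3)
  fit <- msnkit:::.pls1_fit(X, y, ncomp = 3, scale = TRUE)
  mo <- mixOmics::pls(X, y, ncomp = 3, mode = "regression", scale = TRUE)
  for (c in 1:3) {
    mine <- msnkit:::.pls1_predict(fit, X, c)
    theirs <- predict(mo, X)$predict[, 1, c]
    expect_equal(mine, unname(theirs), tolerance = 1e-10)
  }
})

test_that("cross-validation partitions are valid and selection is seed-stable", {
  set.seed(76)
  X <- matrix(rnorm(18 * 10), 18, 10)
  colnames(X) <- paste0("n", 1:10)
  y <- rnorm(18)
  s1 <- pls_cv_select(X, y, c_max = 3, n_instances = 4, k = 9, seed = 5)
  s2 <- pls_cv_select(X, y, c_max = 3, n_instances = 4, k = 9, seed = 5)
  expect_identical(s1$q2_curves, s2$q2_curves)
  expect_equal(sum(s1$selection_counts$count), 4)
  expect_error(pls_cv_select(X[1:17, ], y[1:17], k = 9), "2 subjects")
})

test_that("component selection finds no model under the null", {
  co <- tiny_cohort(80, seed = 77)  # behavior_effect = 0
  X <- nodal_metric_matrix(co, "msn10", 0.4, "strength")
  Xr <- residualize_confounds(X, co$age, co$sex)
  sel <- pls_cv_select(Xr, co$cog_comp, c_max = 5, n_instances = 10,
                       k = 9, seed = 6)
  expect_equal(sel$chosen_c, 0)
  expect_null(sel$final)
  expect_equal(nrow(tidy(sel)), 0)
  expect_true(is.na(glance(sel)$variance_explained))
})

test_that("component selection recovers a strong linear signal", {
  co <- tiny_cohort(80, seed = 78)
  X <- nodal_metric_matrix(co, "msn10", 0.4, "strength")
  Xr <- residualize_confounds(X, co$age, co$sex)
  set.seed(79)
  y <- 2 * scale(Xr[, 5]) + scale(Xr[, 20]) - scale(Xr[, 40]) +
    rnorm(80, sd = 0.2)
  sel <- pls_cv_select(Xr, as.numeric(y), c_max = 5, n_instances = 10,
                       k = 9, seed = 7)
  expect_gte(sel$chosen_c, 1)
  expect_gt(sel$q2_at_chosen, 0.5)
  expect_gt(glance(sel)$variance_explained, 0.5)
  expect_equal(nrow(tidy(sel)), 68)
})

test_that("stratified variant balances training bins and stays deterministic", {
  set.seed(80)
  X <- matrix(rnorm(60 * 8), 60, 8)
  colnames(X) <- paste0("n", 1:8)
  y <- rnorm(60)
  s1 <- pls_cv_select(X, y, c_max = 3, n_instances = 5, k = 5, seed = 8,
                      stratified = TRUE, n_bins = 4)
  s2 <- pls_cv_select(X, y, c_max = 3, n_instances = 5, k = 5, seed = 8,
                      stratified = TRUE, n_bins = 4)
  expect_identical(s1$q2_curves, s2$q2_curves)
  bins <- msnkit:::.equal_count_bins(y, 4)
  expect_equal(unname(table(bins)), rep(15L, 4), ignore_attr = TRUE)
  tr <- msnkit:::.stratified_train(1:45, bins)
  expect_true(all(table(bins[tr]) == min(table(bins[1:45]))))
})

test_that("bootstrap weights flag driving nodes and refuse the null model", {
  co <- tiny_cohort(60, seed = 81)
  X <- nodal_metric_matrix(co, "msn10", 0.4, "strength")
  Xr <- residualize_confounds(X, co$age, co$sex)
  set.seed(82)
  y <- as.numeric(3 * scale(Xr[, 10]) + rnorm(60, sd = 0.3))
  bw <- bootstrap_weights(Xr, y, chosen_c = 1, n_boot = 120, seed = 9)
  expect_equal(nrow(bw), 68)
  drive <- bw[10, ]
  expect_true(drive$conf.low > 0 | drive$conf.high < 0)
  expect_equal(which.max(abs(bw$estimate)), 10L)
  expect_error(bootstrap_weights(Xr, y, chosen_c = 0), "no model")
})

test_that("BCa interval reduces to the percentile interval when z0 = a = 0", {
  # symmetric bootstrap distribution about the point estimate, symmetric
  # jackknife: bias correction and acceleration vanish
  tb <- c(seq(-1, -0.1, by = 0.1), seq(0.1, 1, by = 0.1))
  th <- 0
  jack <- c(seq(-0.5, -0.05, by = 0.05), seq(0.05, 0.5, by = 0.05))
  ci <- msnkit:::.bca_interval(tb, th, jack, conf = 0.9)
  expect_equal(ci[["z0"]], 0)
  expect_equal(ci[["accel"]], 0)
  expect_equal(unname(ci[c("low", "high")]),
               unname(quantile(tb, c(0.05, 0.95), type = 6)))
})

test_that("degenerate bootstrap distribution yields a zero-width interval", {
  ci <- msnkit:::.bca_interval(rep(0.4, 50), 0.4, rep(0.4, 10))
  expect_equal(ci[["low"]], 0.4)
  expect_equal(ci[["high"]], 0.4)
})
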