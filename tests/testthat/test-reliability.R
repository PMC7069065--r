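# Reliability analyses: intermodel hierarchy, test-retest, group average.

test_that("group network is the element-wise mean of thresholded networks", {
  co <- tiny_cohort(2, seed = 51, n_regions = 10)
  msns <- lapply(co$features, build_msn)
  grp <- build_group_network(msns, 0.4)
  t1 <- threshold_density(msns[[1]], 0.4)$weighted
  t2 <- threshold_density(msns[[2]], 0.4)$weighted
  expect_equal(grp$weights, (t1 + t2) / 2)
  expect_true(isSymmetric(grp$weights))
  expect_true(all(diag(grp$weights) == 0))
  # raw mode averages first, thresholds after
  grp_raw <- build_group_network(msns, 0.4, from = "raw")
  expect_equal(grp_raw$weights,
               threshold_density((unclass(msns[[1]]) + unclass(msns[[2]])) / 2,
                                 0.4)$weighted)
})

test_that("identical subjects give a group network equal to each individual", {
  cfg <- cohort_config(n_subjects = 3, seed = 52, subject_sd = 0,
                       modality_noise = c(T1w = 0, T2w = 0, DWI = 0))
  co <- generate_cohort(cfg)
  msns <- lapply(co$features, build_msn)
  grp <- build_group_network(msns, 0.4)
  expect_equal(grp$weights, threshold_density(msns[[1]], 0.4)$weighted)
  res <- run_subject_vs_group(co, "msn10", densities = 0.4)
  expect_true(all(res$records$r_all == 1))
  expect_true(all(res$records$prop_replicated == 1))
})

test_that("intermodel analysis compares only against the 10-feature reference", {
  co <- tiny_cohort(5, seed = 53)
  res <- run_intermodel(co, densities = c(0.2, 0.4))
  expect_setequal(unique(res$records$contrast),
                  c("msn10_vs_msn8", "msn10_vs_msn7"))
  expect_equal(nrow(res$records), 5 * 2 * 2)
  expect_true(all(res$records$r_all >= -1 & res$records$r_all <= 1))
  expect_true(all(res$records$prop_replicated >= 0 &
                  res$records$prop_replicated <= 1))
  # summary bookkeeping
  s <- res$summary
  expect_true(all(s$n == 5))
  expect_equal(nrow(s), 2 * 2 * 4)  # contrast x density x statistic
})

test_that("dropping information-free features preserves the MSN almost exactly", {
  # make FA, MD exact copies of retained features: the dropped columns add
  # no information (they only reweight CT and SA in the region-pair Pearson),
  # so 10-vs-8 similarity must rise far above its default-cohort level
  co <- tiny_cohort(3, seed = 54)
  res_default <- run_intermodel(co, densities = 0.4)
  co$features <- lapply(co$features, function(ft) {
    ft$FA <- ft$CT
    ft$MD <- ft$SA
    ft
  })
  res <- run_intermodel(co, densities = 0.4)
  pick <- function(r) r$records$r_all[r$records$contrast == "msn10_vs_msn8"]
  expect_true(all(pick(res) > 0.9))
  expect_true(all(pick(res) > pick(res_default)))
})

test_that("single-subject summaries have n = 1 and SD = 0", {
  co <- tiny_cohort(2, seed = 55)
  res <- run_intermodel(co[1, ], densities = 0.4)
  expect_true(all(res$summary$n == 1))
  expect_true(all(res$summary$sd == 0))
})

test_that("similarity hierarchy: 10-vs-8 exceeds 10-vs-7 on default cohorts", {
  co <- tiny_cohort(20, seed = 56)
  res <- run_intermodel(co, densities = 0.4)
  s <- res$summary
  for (stat in c("r_all", "mantel_r", "prop_replicated")) {
    m8 <- s$mean[s$contrast == "msn10_vs_msn8" & s$statistic == stat]
    m7 <- s$mean[s$contrast == "msn10_vs_msn7" & s$statistic == stat]
    expect_gt(m8, m7)
  }
})

test_that("mean edge correlation is non-decreasing across the density grid", {
  co <- tiny_cohort(10, seed = 57)
  res <- run_intermodel(co, densities = density_grid())
  s <- dplyr::filter(res$summary, statistic == "r_all")
  for (ctr in unique(s$contrast)) {
    m <- s$mean[s$contrast == ctr][order(s$density[s$contrast == ctr])]
    expect_true(all(diff(m) > -0.02))
  }
})

test_that("graph strength decreases as features are added (7 > 8 > 10)", {
  co <- tiny_cohort(15, seed = 58)
  res <- run_intermodel(co, densities = 0.4)
  means <- tapply(res$strength$graph_strength, res$strength$model, mean)
  expect_gt(means[["msn7"]], means[["msn8"]])
  expect_gt(means[["msn8"]], means[["msn10"]])
})

test_that("test-retest similarity is perfect at rho = 1 and increases with rho", {
  co <- tiny_cohort(8, seed = 59)
  co1 <- generate_retest(co, 1)
  res1 <- run_test_retest(co1, "msn10", densities = 0.4)
  expect_equal(res1$records$r_all, rep(1, 8), tolerance = 1e-12)
  expect_true(all(res1$records$prop_replicated == 1))

  r_means <- vapply(c(0, 0.5, 0.9), function(rho) {
    cor_ <- generate_retest(co, rho, seed = 60)
    res <- run_test_retest(cor_, "msn10", densities = 0.4)
    mean(res$records$r_all)
  }, numeric(1))
  expect_true(all(diff(r_means) > 0))
})

test_that("subjects without retest are skipped with a warning; none is an error", {
  co <- generate_retest(tiny_cohort(4, seed = 61), 0.8)
  co$retest_features[2] <- list(NULL)
  expect_warning(res <- run_test_retest(co, "msn10", densities = 0.4),
                 "skipped")
  expect_equal(unique(res$summary$n), 3L)
  co_none <- tiny_cohort(3, seed = 62)
  expect_error(run_test_retest(co_none), "retest")
})

test_that("subject-vs-group similarity exceeds the 10-vs-7 intermodel level", {
  co <- tiny_cohort(15, seed = 63)
  grp <- run_subject_vs_group(co, "msn10", densities = 0.4)
  im <- run_intermodel(co, densities = 0.4)
  m_grp <- grp$summary$mean[grp$summary$statistic == "r_all"]
  m_im7 <- im$summary$mean[im$summary$contrast == "msn10_vs_msn7" &
                           im$summary$statistic == "r_all"]
  expect_gt(m_grp, m_im7)
})
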