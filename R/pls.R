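# Brain-behavior stage: EF summary via PCA, confound residualization, PLS1
# regression with Q^2-based component selection over repeated k-fold CV, the
# stratified-bin training variant, and BCa bootstrap predictor weights.

#' Executive-function summary score via PCA
#'
#' Principal component analysis on the correlation scale of the three EF
#' subtest scores. The first component is retained only if its eigenvalue
#' exceeds 1 and all three subtests load with a common sign (flipped so the
#' loadings are positive, making higher scores mean better EF); otherwise an
#' error explains which retention rule failed.
#'
#' @param ef_scores N x 3 numeric matrix or data frame of subtest scores
#'   (complete, each column with nonzero variance).
#' @return List with `scores` (standardized first-component scores, length
#'   N), `eigenvalue` and `loadings`.
#' @export
ef_summary <- function(ef_scores) {
  m <- as.matrix(ef_scores)
  if (ncol(m) != 3L) stop("expected 3 EF subtest columns", call. = FALSE)
  if (anyNA(m)) stop("EF scores contain missing values", call. = FALSE)
  sds <- apply(m, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance EF column(s): ",
         paste(colnames(m)[sds == 0], collapse = ", "), call. = FALSE)
  }
  pc <- stats::prcomp(m, center = TRUE, scale. = TRUE)
  ev1 <- pc$sdev[1]^2
  if (ev1 <= 1) {
    stop(sprintf(paste0("first principal component eigenvalue %.3f <= 1; ",
                        "retention rule not met - no common EF component"),
                 ev1), call. = FALSE)
  }
  load1 <- pc$rotation[, 1]
  if (sum(load1 > 0) < 3L) load1 <- -load1
  if (any(load1 <= 0)) {
    stop("EF subtests do not all load with a common sign on the first ",
         "component", call. = FALSE)
  }
  scores <- as.numeric(scale(m, center = pc$center, scale = pc$scale) %*% load1)
  list(scores = as.numeric(scale(scores)), eigenvalue = ev1, loadings = load1)
}

#' Per-subject nodal metric matrix
#'
#' Extracts one nodal metric from each subject's thresholded MSN: `strength`
#' (sum of incident edge weights), `degree` (count of incident suprathreshold
#' edges; under exact equal-density thresholding this varies little across
#' subjects) or `normalized_strength` (strength / degree).
#'
#' @param cohort An `msn_cohort`.
#' @param model Feature model name.
#' @param density Edge density.
#' @param metric One of `"strength"`, `"degree"`, `"normalized_strength"`.
#' @return N x n_regions numeric matrix, subjects as rows, regions as named
#'   columns.
#' @export
nodal_metric_matrix <- function(cohort, model = "msn10", density = 0.40,
                                metric = c("strength", "degree",
                                           "normalized_strength")) {
  metric <- match.arg(metric)
  spec <- .as_feature_set(model)
  rows <- lapply(cohort$features, function(ft) {
    thr <- threshold_density(build_msn(subset_features(ft, spec)), density)
    s <- nodal_strength(thr)
    deg <- rowSums(thr$binary)
    switch(metric,
           strength = s,
           degree = deg,
           normalized_strength = s / pmax(deg, 1))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- cohort$subject_id
  out
}

#' Regress confounds out of a nodal predictor matrix
#'
#' Removes age, sex and the age x sex interaction from every node's metric by
#' ordinary least squares, returning the residuals. The cognitive outcome is
#' deliberately left untouched (outcome scores are assumed already
#' age-adjusted).
#'
#' @param metric N x n_regions matrix (subjects as rows).
#' @param age Numeric vector, years.
#' @param sex Factor or character (`F`/`M`).
#' @return Residual matrix of the same shape (each column mean ~0), class
#'   `predictor_matrix`.
#' @export
residualize_confounds <- function(metric, age, sex) {
  metric <- as.matrix(metric)
  if (anyNA(metric) || anyNA(age) || anyNA(sex)) {
    stop("metric and covariates must be complete", call. = FALSE)
  }
  sex <- factor(sex)
  if (nlevels(sex) < 2L) {
    stop("confound design matrix (intercept, age, sex, age:sex) is rank ",
         "deficient (is the cohort single-sex?)", call. = FALSE)
  }
  design <- stats::model.matrix(~ age * sex)
  qr_d <- qr(design)
  if (qr_d$rank < ncol(design)) {
    stop("confound design matrix (intercept, age, sex, age:sex) is rank ",
         "deficient (is the cohort single-sex?)", call. = FALSE)
  }
  res <- qr.resid(qr_d, metric)
  dimnames(res) <- dimnames(metric)
  class(res) <- c("predictor_matrix", class(res))
  res
}

#' Cross-validated R-squared (the Q-squared statistic)
#'
#' Q^2 = 1 - PRESS / TSS, where PRESS is the predictive residual error sum of
#' squares of the out-of-fold predictions and TSS the total sum of squares
#' about the grand mean of the observed outcomes. Q^2 = 1 for perfect
#' prediction, 0 for a model no better than predicting the mean, and can be
#' arbitrarily negative.
#'
#' @param y_true Observed outcomes.
#' @param y_pred Out-of-fold predictions, same length, each subject predicted
#'   exactly once.
#' @return Q^2 (a single number, <= 1).
#' @export
q_squared <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred))
  tss <- sum((y_true - mean(y_true))^2)
  if (tss == 0) stop("zero total sum of squares; Q^2 undefined", call. = FALSE)
  1 - sum((y_pred - y_true)^2) / tss
}

# ---- PLS1 (NIPALS) -------------------------------------------------------

# Univariate-response PLS. X is centered (and by default scaled to unit SD);
# components are extracted as directions of maximal predictor-response
# covariance with deflation of X. Returns cumulative regression coefficients
# for every component count 1..ncomp so nested models come from one fit.
.pls1_fit <- function(X, y, ncomp, scale = TRUE) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  ncomp <- min(ncomp, p, n - 1L)
  x_mean <- colMeans(X)
  x_sd <- if (scale) apply(X, 2L, stats::sd) else rep(1, p)
  x_sd[x_sd == 0] <- 1
  Xc <- sweep(sweep(X, 2L, x_mean), 2L, x_sd, "/")
  y_mean <- mean(y)
  yc <- y - y_mean

  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp); Q <- numeric(ncomp)
  Xd <- Xc; yd <- yc
  used <- 0L
  for (c in seq_len(ncomp)) {
    w <- crossprod(Xd, yd)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    t_sc <- Xd %*% w
    tt <- sum(t_sc^2)
    if (tt < 1e-12) break
    p_load <- crossprod(Xd, t_sc) / tt
    q_load <- sum(yd * t_sc) / tt
    Xd <- Xd - t_sc %*% t(p_load)
    yd <- yd - q_load * t_sc
    W[, c] <- w; P[, c] <- p_load; Q[c] <- q_load
    used <- c
  }
  # cumulative coefficients on the standardized predictor scale
  B <- matrix(0, p, ncomp)
  if (used > 0L) {
    for (c in seq_len(used)) {
      Wc <- W[, seq_len(c), drop = FALSE]
      Pc <- P[, seq_len(c), drop = FALSE]
      B[, c] <- Wc %*% solve(crossprod(Pc, Wc), Q[seq_len(c)])
    }
    if (used < ncomp) for (c in (used + 1L):ncomp) B[, c] <- B[, used]
  }
  rownames(B) <- colnames(X)
  list(B = B, x_mean = x_mean, x_sd = x_sd, y_mean = y_mean,
       ncomp = ncomp, used = used)
}

.pls1_predict <- function(fit, X, ncomp) {
  Xc <- sweep(sweep(as.matrix(X), 2L, fit$x_mean), 2L, fit$x_sd, "/")
  if (ncomp == 0L) return(rep(fit$y_mean, nrow(Xc)))
  as.numeric(Xc %*% fit$B[, ncomp]) + fit$y_mean
}

# ---- component selection over repeated k-fold CV -------------------------

#' PLS component selection by repeated cross-validated Q-squared
#'
#' For each of `n_instances` random k-fold partitions, fits a PLS1 regression
#' of the outcome on the nodal predictor matrix for every candidate component
#' count c = 0..`c_max` (c = 0 is the intercept-only model predicting the
#' training-fold mean), pools the out-of-fold predictions into one Q^2 per
#' (instance, c) and records which c maximized Q^2. The final retained
#' component count is the modal argmax over instances; when zero components
#' win most often, no predictive model is built. With `stratified = TRUE`,
#' subjects are binned into `n_bins` equal-count outcome bins and each
#' training set is rebuilt from equal-sized random samples per bin, guarding
#' against under-representation of the distribution tails.
#'
#' @param X N x p predictor matrix (e.g. from [residualize_confounds()]).
#' @param y Outcome vector, length N (not residualized).
#' @param c_max Maximum component count considered (default 10).
#' @param n_instances Number of CV repetitions (default 100).
#' @param k Folds per instance (default 9); requires N >= 2k.
#' @param seed Integer seed; the whole selection is deterministic given it.
#' @param stratified Use the equal-count outcome-bin training variant.
#' @param n_bins Number of outcome bins for the stratified variant.
#' @param scale Standardize predictors inside PLS (default TRUE).
#' @return A `pls_selection` object: `selection_counts` (tibble c, count),
#'   `chosen_c`, `q2_curves` (instance x c tibble), `q2_at_chosen` (mean
#'   pooled Q^2 at the chosen c), and when `chosen_c > 0` a `final` list with
#'   per-node `coefficients` (standardized scale), `intercept` and in-sample
#'   `variance_explained`.
#' @export
pls_cv_select <- function(X, y, c_max = 10, n_instances = 100, k = 9,
                          seed = 1L, stratified = FALSE, n_bins = 4,
                          scale = TRUE) {
  X <- as.matrix(X)
  N <- nrow(X)
  if (!all(is.finite(X))) stop("non-finite predictor values", call. = FALSE)
  if (length(y) != N) stop("y length must match nrow(X)", call. = FALSE)
  if (N < 2 * k) {
    stop("need at least 2 subjects per fold (N >= 2k)", call. = FALSE)
  }
  if (c_max < 1) stop("c_max must be >= 1", call. = FALSE)

  bins <- if (stratified) .equal_count_bins(y, n_bins) else NULL

  q2_curves <- purrr::map_dfr(seq_len(n_instances), function(inst) {
    withr::with_seed(seed + inst, {
      fold <- sample(rep(seq_len(k), length.out = N))
      preds <- matrix(NA_real_, N, c_max + 1L)
      for (f in seq_len(k)) {
        test_idx <- which(fold == f)
        train_idx <- which(fold != f)
        if (stratified) train_idx <- .stratified_train(train_idx, bins)
        if (length(test_idx) < 2L || length(train_idx) < 2L) {
          stop("fold with fewer than 2 subjects", call. = FALSE)
        }
        fit <- .pls1_fit(X[train_idx, , drop = FALSE], y[train_idx],
                         ncomp = c_max, scale = scale)
        for (c in 0:c_max) {
          preds[test_idx, c + 1L] <-
            .pls1_predict(fit, X[test_idx, , drop = FALSE], min(c, fit$ncomp))
        }
      }
      tibble::tibble(
        instance = inst, ncomp = 0:c_max,
        q2 = vapply(0:c_max, function(c) q_squared(y, preds[, c + 1L]),
                    numeric(1))
      )
    })
  })

  argmax <- dplyr::summarise(
    dplyr::group_by(q2_curves, .data$instance),
    best_c = .data$ncomp[which.max(.data$q2)], .groups = "drop"
  )
  counts <- tibble::tibble(ncomp = 0:c_max)
  tab <- table(factor(argmax$best_c, levels = 0:c_max))
  counts$count <- as.integer(tab)
  chosen_c <- as.integer(names(tab)[which.max(tab)])

  q2_at_chosen <- mean(q2_curves$q2[q2_curves$ncomp == chosen_c])

  final <- NULL
  if (chosen_c > 0) {
    fit <- .pls1_fit(X, y, ncomp = chosen_c, scale = scale)
    fitted_vals <- .pls1_predict(fit, X, chosen_c)
    final <- list(
      coefficients = stats::setNames(fit$B[, chosen_c], colnames(X)),
      intercept = fit$y_mean,
      variance_explained = 1 - sum((y - fitted_vals)^2) /
        sum((y - mean(y))^2),
      fit = fit
    )
  }
  structure(
    list(selection_counts = counts, chosen_c = chosen_c,
         q2_curves = q2_curves, q2_at_chosen = q2_at_chosen, final = final,
         params = list(c_max = c_max, n_instances = n_instances, k = k,
                       seed = seed, stratified = stratified, n_bins = n_bins,
                       scale = scale, n = N, p = ncol(X))),
    class = "pls_selection"
  )
}

# equal-count outcome bins (quartiles by default); ties broken by rank order
.equal_count_bins <- function(y, n_bins) {
  r <- rank(y, ties.method = "first")
  as.integer(ceiling(r / (length(y) / n_bins)))
}

# equal-sized random samples per outcome bin from the available training rows
.stratified_train <- function(train_idx, bins) {
  by_bin <- split(train_idx, bins[train_idx])
  m <- min(lengths(by_bin))
  sort(unlist(lapply(by_bin, function(ix) {
    if (length(ix) == m) ix else sample(ix, m)
  }), use.names = FALSE))
}

#' @export
print.pls_selection <- function(x, ...) {
  cat(sprintf("<pls_selection> %d instances of %d-fold CV, c_max = %d\n",
              x$params$n_instances, x$params$k, x$params$c_max))
  cat(sprintf("  chosen components: %d (selected in %d/%d instances)\n",
              x$chosen_c,
              x$selection_counts$count[x$selection_counts$ncomp == x$chosen_c],
              x$params$n_instances))
  if (x$chosen_c == 0) {
    cat("  no predictive model built (intercept-only wins)\n")
  } else {
    cat(sprintf("  in-sample variance explained: %.3f\n",
                x$final$variance_explained))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a PLS selection result
#'
#' One row per predictor (node) with the final-model coefficient on the
#' standardized predictor scale; if bootstrap intervals have been attached
#' via [bootstrap_weights()], `conf.low`/`conf.high` are included. With
#' `chosen_c = 0` an empty tibble is returned (no model was built).
#'
#' @param x A `pls_selection`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate` (and interval columns if
#'   available).
#' @export
tidy.pls_selection <- function(x, ...) {
  if (x$chosen_c == 0 || is.null(x$final)) {
    return(tibble::tibble(term = character(), estimate = numeric()))
  }
  out <- tibble::tibble(term = names(x$final$coefficients),
                        estimate = unname(x$final$coefficients))
  if (!is.null(x$bootstrap)) {
    out <- dplyr::left_join(out, x$bootstrap, by = "term")
  }
  out
}

#' One-row summary of a PLS selection result
#'
#' @param x A `pls_selection`.
#' @param ... Unused.
#' @return Tibble with `chosen_c`, its selection count, `n_instances`,
#'   `q2_at_chosen` and (when a model was built) `variance_explained`.
#' @export
glance.pls_selection <- function(x, ...) {
  tibble::tibble(
    chosen_c = x$chosen_c,
    count_chosen = x$selection_counts$count[
      x$selection_counts$ncomp == x$chosen_c],
    n_instances = x$params$n_instances,
    q2_at_chosen = x$q2_at_chosen,
    variance_explained = if (x$chosen_c > 0) x$final$variance_explained
                         else NA_real_
  )
}

# ---- BCa bootstrap of predictor weights ----------------------------------

#' BCa bootstrap intervals for PLS predictor weights
#'
#' Resamples subjects with replacement, refits the PLS model with the chosen
#' component count, sign-aligns each resampled weight vector against the
#' point estimate (dot-product convention; PLS components have arbitrary
#' sign), and builds bias-corrected and accelerated intervals per node: the
#' bias correction z0 comes from the proportion of bootstrap weights below
#' the point estimate, the acceleration a from jackknife skewness. With
#' z0 = 0 and a = 0 the interval reduces to the percentile interval.
#'
#' @param X N x p predictor matrix.
#' @param y Outcome vector.
#' @param chosen_c Component count (>= 1) — typically
#'   `pls_selection$chosen_c`.
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param seed Integer seed.
#' @param conf Confidence level (default 0.95).
#' @param scale Standardize predictors inside PLS.
#' @return Tibble with `term`, `estimate`, `conf.low`, `conf.high`, `z0`,
#'   `accel`.
#' @export
bootstrap_weights <- function(X, y, chosen_c, n_boot = 1000, seed = 1L,
                              conf = 0.95, scale = TRUE) {
  if (chosen_c < 1) {
    stop("chosen_c = 0: no model to bootstrap", call. = FALSE)
  }
  X <- as.matrix(X)
  N <- nrow(X)
  fit0 <- .pls1_fit(X, y, ncomp = chosen_c, scale = scale)
  w0 <- fit0$B[, chosen_c]

  boot_w <- withr::with_seed(seed, {
    t(vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(N, N, replace = TRUE)
      wb <- .pls1_fit(X[idx, , drop = FALSE], y[idx],
                      ncomp = chosen_c, scale = scale)$B[, chosen_c]
      if (sum(wb * w0) < 0) wb <- -wb
      wb
    }, numeric(length(w0))))
  })

  jack_w <- t(vapply(seq_len(N), function(i) {
    wj <- .pls1_fit(X[-i, , drop = FALSE], y[-i],
                    ncomp = chosen_c, scale = scale)$B[, chosen_c]
    if (sum(wj * w0) < 0) wj <- -wj
    wj
  }, numeric(length(w0))))

  res <- purrr::map_dfr(seq_along(w0), function(j) {
    ci <- .bca_interval(boot_w[, j], w0[j], jack_w[, j], conf)
    tibble::tibble(term = names(w0)[j], estimate = unname(w0[j]),
                   conf.low = ci[["low"]], conf.high = ci[["high"]],
                   z0 = ci[["z0"]], accel = ci[["accel"]])
  })
  res
}

# BCa interval for one statistic: bias correction z0 from the bootstrap
# distribution's position relative to the point estimate, acceleration from
# jackknife skewness. z0 = a = 0 reduces to the percentile interval.
.bca_interval <- function(theta_boot, theta_hat, theta_jack, conf = 0.95) {
  n_boot <- length(theta_boot)
  if (stats::sd(theta_boot) == 0) {
    return(c(low = theta_boot[1], high = theta_boot[1], z0 = 0, accel = 0))
  }
  prop <- (sum(theta_boot < theta_hat) + 0.5 * sum(theta_boot == theta_hat)) /
    n_boot
  prop <- min(max(prop, 1 / (n_boot + 1)), n_boot / (n_boot + 1))
  z0 <- stats::qnorm(prop)
  jm <- mean(theta_jack)
  d <- jm - theta_jack
  denom <- sum(d^2)^1.5
  a <- if (denom == 0) 0 else sum(d^3) / (6 * denom)
  alpha <- (1 - conf) / 2
  adj <- function(z_alpha) {
    stats::pnorm(z0 + (z0 + z_alpha) / (1 - a * (z0 + z_alpha)))
  }
  qs <- stats::quantile(theta_boot,
                        c(adj(stats::qnorm(alpha)), adj(stats::qnorm(1 - alpha))),
                        type = 6, names = FALSE)
  c(low = qs[1], high = qs[2], z0 = z0, accel = a)
}
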