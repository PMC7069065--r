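# The three reliability studies: intermodel (10 vs 8, 10 vs 7), intrasubject
# test-retest, and subject-vs-group-average, across the density grid.

#' Default proportional-density grid
#'
#' Densities 0.05 to 0.40 in steps of 0.05 — the range over which results
#' are summarized, with the named endpoints 5% (sparsest) and 40% (densest)
#' reported individually.
#'
#' @return Numeric vector of densities.
#' @export
density_grid <- function() seq(0.05, 0.40, by = 0.05)

# per-subject thresholded networks for one model across densities
.subject_networks <- function(ft, model, densities) {
  spec <- .as_feature_set(model)
  msn <- build_msn(subset_features(ft, spec))
  stats::setNames(lapply(densities, function(d) threshold_density(msn, d)),
                  sprintf("%.2f", densities))
}

.summarise_records <- function(records, analysis) {
  long <- tidyr::pivot_longer(
    records,
    cols = dplyr::any_of(c("r_all", "r_nonzero", "mantel_r", "prop_replicated")),
    names_to = "statistic", values_to = "value"
  )
  out <- dplyr::summarise(
    dplyr::group_by(long, .data$contrast, .data$density, .data$statistic),
    mean = mean(.data$value, na.rm = TRUE),
    sd = stats::sd(.data$value, na.rm = TRUE),
    n = sum(!is.na(.data$value)),
    .groups = "drop"
  )
  out$sd[out$n == 1L] <- 0
  tibble::add_column(out, analysis = analysis, .before = 1L)
}

#' Intermodel similarity analysis
#'
#' Compares each subject's 10-feature MSN (the "gold standard") with the
#' 8-feature and with the 7-feature MSN — hierarchically, never 8 vs 7 —
#' at every density, emitting all four similarity statistics per subject and
#' M +/- SD summaries, plus paired-t effect sizes for the graph-strength
#' differences between models.
#'
#' @param cohort An `msn_cohort` tibble.
#' @param densities Density grid (default [density_grid()]).
#' @return A list with `records` (one row per subject x contrast x density),
#'   `summary` (M +/- SD per contrast x density x statistic) and
#'   `effect_sizes` (graph-strength paired-t effect size per contrast x
#'   density).
#' @export
run_intermodel <- function(cohort, densities = density_grid()) {
  models <- c("msn10", "msn8", "msn7")
  usable <- !vapply(cohort$features, is.null, logical(1))
  if (any(!usable)) {
    warning(sum(!usable), " subject(s) without feature data skipped",
            call. = FALSE)
  }
  sub <- cohort[usable, ]
  nets <- lapply(sub$features, function(ft) {
    lapply(stats::setNames(models, models),
           function(m) .subject_networks(ft, m, densities))
  })
  records <- purrr::map_dfr(seq_len(nrow(sub)), function(i) {
    purrr::map_dfr(c("msn8", "msn7"), function(reduced) {
      purrr::map_dfr(seq_along(densities), function(k) {
        rec <- similarity_record(nets[[i]]$msn10[[k]], nets[[i]][[reduced]][[k]])
        tibble::add_column(rec,
          subject_id = sub$subject_id[i],
          contrast = paste0("msn10_vs_", reduced),
          density = densities[k], .before = 1L)
      })
    })
  })
  strength <- purrr::map_dfr(seq_len(nrow(sub)), function(i) {
    purrr::map_dfr(models, function(m) {
      tibble::tibble(
        subject_id = sub$subject_id[i], model = m, density = densities,
        graph_strength = vapply(nets[[i]][[m]], graph_strength, numeric(1))
      )
    })
  })
  effect_sizes <- if (nrow(sub) >= 3L) {
    purrr::map_dfr(c("msn8", "msn7"), function(reduced) {
      purrr::map_dfr(densities, function(d) {
        a <- strength$graph_strength[strength$model == "msn10" & strength$density == d]
        b <- strength$graph_strength[strength$model == reduced & strength$density == d]
        es <- paired_effect_size(a, b, label = paste0("msn10_vs_", reduced))
        tibble::add_column(es, density = d, .after = "contrast")
      })
    })
  } else {
    tibble::tibble(contrast = character(), density = numeric(),
                   t = numeric(), df = numeric(), r_effect = numeric())
  }
  list(records = records,
       summary = .summarise_records(records, "intermodel"),
       strength = strength,
       effect_sizes = effect_sizes)
}

#' Test-retest reliability analysis
#'
#' For every subject with a retest session, compares the session-1 MSN with
#' the retest MSN of the same model at each density, using all four
#' similarity statistics.
#'
#' @param cohort An `msn_cohort` with `retest_features` filled (see
#'   [generate_retest()]).
#' @param models Character vector of feature models (default all three).
#' @param densities Density grid.
#' @return A list with `records` and `summary` (contrast = model name).
#' @export
run_test_retest <- function(cohort, models = c("msn10", "msn8", "msn7"),
                            densities = density_grid()) {
  has_retest <- !vapply(cohort$retest_features, is.null, logical(1))
  if (!any(has_retest)) {
    stop("no subject has a retest session; run generate_retest() or provide ",
         "retest tables", call. = FALSE)
  }
  if (any(!has_retest)) {
    warning(sum(!has_retest), " subject(s) without retest session skipped",
            call. = FALSE)
  }
  sub <- cohort[has_retest, ]
  records <- purrr::map_dfr(seq_len(nrow(sub)), function(i) {
    purrr::map_dfr(models, function(m) {
      nets1 <- .subject_networks(sub$features[[i]], m, densities)
      nets2 <- .subject_networks(sub$retest_features[[i]], m, densities)
      purrr::map_dfr(seq_along(densities), function(k) {
        rec <- similarity_record(nets1[[k]], nets2[[k]])
        tibble::add_column(rec,
          subject_id = sub$subject_id[i], contrast = m,
          density = densities[k], .before = 1L)
      })
    })
  })
  list(records = records, summary = .summarise_records(records, "retest"))
}

#' Group-average network
#'
#' Element-wise mean over subjects of the per-subject networks for one model
#' at one density. `from = "thresholded"` (default) averages the thresholded
#' weighted matrices; `from = "raw"` averages the unthresholded MSNs and
#' thresholds the mean. The mean of thresholded matrices is generally not
#' itself at density d.
#'
#' @param msns List of `msn_matrix` objects (one per subject).
#' @param d Density.
#' @param from `"thresholded"` or `"raw"`.
#' @return A `group_network`: list with `weights` (mean matrix), `density`,
#'   `from` and `n` (number of subjects averaged).
#' @export
build_group_network <- function(msns, d, from = c("thresholded", "raw")) {
  from <- match.arg(from)
  if (length(msns) == 0) stop("no networks to average", call. = FALSE)
  mats <- if (from == "thresholded") {
    lapply(msns, function(m) threshold_density(m, d)$weighted)
  } else {
    lapply(msns, .net_weights)
  }
  w <- Reduce(`+`, mats) / length(mats)
  if (from == "raw") w <- threshold_density(w, d)$weighted
  structure(list(weights = w, density = d, from = from, n = length(mats)),
            class = "group_network")
}

#' Subject-versus-group-average similarity analysis
#'
#' Compares each subject's thresholded MSN with the cohort's group-average
#' network for the same model and density (the subject is included in the
#' group mean). For the binary replication proportion the group mean is
#' itself thresholded back to density d; the subject's network is the
#' reference.
#'
#' @inheritParams run_test_retest
#' @param group_from Passed to [build_group_network()] (`"thresholded"` or
#'   `"raw"`).
#' @return A list with `records`, `summary` and `group_networks` (nested list
#'   model -> density).
#' @export
run_subject_vs_group <- function(cohort, models = c("msn10", "msn8", "msn7"),
                                 densities = density_grid(),
                                 group_from = "thresholded") {
  usable <- !vapply(cohort$features, is.null, logical(1))
  sub <- cohort[usable, ]
  out_groups <- list()
  records <- purrr::map_dfr(models, function(m) {
    spec <- .as_feature_set(m)
    msns <- lapply(sub$features, function(ft) build_msn(subset_features(ft, spec)))
    purrr::map_dfr(densities, function(d) {
      grp <- build_group_network(msns, d, from = group_from)
      out_groups[[m]][[sprintf("%.2f", d)]] <<- grp
      grp_thr <- threshold_density(grp$weights, d)
      purrr::map_dfr(seq_len(nrow(sub)), function(i) {
        thr_i <- threshold_density(msns[[i]], d)
        tibble::tibble(
          subject_id = sub$subject_id[i], contrast = m, density = d,
          r_all = edge_correlation(thr_i, grp$weights, mode = "all"),
          r_nonzero = tryCatch(
            edge_correlation(thr_i, grp$weights, mode = "nonzero"),
            error = function(e) NA_real_),
          mantel_r = mantel_statistic(thr_i, grp$weights)$r,
          prop_replicated = replication_proportion(thr_i, grp_thr)
        )
      })
    })
  })
  list(records = records, summary = .summarise_records(records, "group"),
       group_networks = out_groups)
}
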