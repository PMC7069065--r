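# End-to-end orchestration: config, stage sequencing, output writing,
# run manifest.

#' Pipeline run configuration
#'
#' Bundles everything one reproducible run needs: the cohort source (a
#' [cohort_config()] for synthetic data, or a directory written by
#' [write_cohort()]), the feature models and density grid, the analyses to
#' run, the prediction settings, and a single seed from which every stage
#' derives its own sub-seed (stage seeds are `seed + 1000 * stage_index`,
#' so stages are reproducible in isolation).
#'
#' @param cohort A [cohort_config()] or a directory path.
#' @param models Subset of `c("msn10", "msn8", "msn7")`.
#' @param densities Density grid in (0, 1].
#' @param analyses Subset of `c("intermodel", "retest", "group", "predict")`.
#' @param seed Integer master seed.
#' @param output_dir Where outputs are written.
#' @param retest_rho Reliability used if a retest session must be generated.
#' @param predict Options list for the predict stage: `metric`, `model`,
#'   `density`, `outcome` (`"cog_comp"` or `"ef"`), `instances`, `folds`,
#'   `c_max`, `stratified`, `n_bins`, `n_boot`.
#' @return A `run_config` list.
#' @export
run_config <- function(cohort = cohort_config(),
                       models = c("msn10", "msn8", "msn7"),
                       densities = density_grid(),
                       analyses = c("intermodel", "retest", "group"),
                       seed = 1L,
                       output_dir = tempfile("msnkit_run_"),
                       retest_rho = NULL,
                       predict = list()) {
  stopifnot(all(densities > 0 & densities <= 1))
  if (length(models) == 0 || length(analyses) == 0) {
    stop("at least one model and one analysis required", call. = FALSE)
  }
  analyses <- match.arg(analyses,
                        c("intermodel", "retest", "group", "predict"),
                        several.ok = TRUE)
  models <- match.arg(models, c("msn10", "msn8", "msn7"), several.ok = TRUE)
  predict <- utils::modifyList(
    list(metric = "strength", model = "msn10", density = 0.40,
         outcome = "cog_comp", instances = 100, folds = 9, c_max = 10,
         stratified = FALSE, n_bins = 4, n_boot = 500),
    predict
  )
  structure(
    list(cohort = cohort, models = models, densities = densities,
         analyses = analyses, seed = as.integer(seed),
         output_dir = output_dir, retest_rho = retest_rho,
         predict = predict),
    class = "run_config"
  )
}

.write_output <- function(df, path, seed) {
  writeLines(sprintf("# seed: %d", seed), path)
  readr::write_csv(df, path, append = TRUE, col_names = TRUE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes the requested stages in dependency order — cohort acquisition,
#' network construction, then each analysis — writing every tabular output
#' as CSV (with the run seed recorded in a leading comment line; read back
#' with `comment = "#"`) and group networks as TSV matrices. Re-running with
#' an identical configuration reproduces all outputs byte-identically; the
#' returned manifest lists every file with its MD5 checksum and row count.
#'
#' @param config A [run_config()].
#' @return The manifest tibble (`file`, `rows`, `md5`), invisibly written to
#'   `manifest.csv` as well.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  written <- character()

  # stage 1: cohort
  if (inherits(config$cohort, "cohort_config")) {
    cohort <- generate_cohort(config$cohort)
  } else if (is.character(config$cohort) && dir.exists(config$cohort)) {
    cohort <- read_cohort(config$cohort)
  } else {
    stop("pipeline stage 'cohort': source must be a cohort_config or an ",
         "existing directory", call. = FALSE)
  }
  message(sprintf("[cohort] n = %d subjects", nrow(cohort)))

  add <- function(df, name) {
    p <- .write_output(df, file.path(out, name), seed)
    written <<- c(written, p)
  }

  if ("intermodel" %in% config$analyses) {
    res <- run_intermodel(cohort, config$densities)
    add(res$records, "intermodel_records.csv")
    add(res$summary, "intermodel_summary.csv")
    add(res$effect_sizes, "intermodel_effect_sizes.csv")
    add(res$strength, "graph_strength.csv")
    message(sprintf("[intermodel] %d record rows", nrow(res$records)))
  }

  if ("retest" %in% config$analyses) {
    has_retest <- any(!vapply(cohort$retest_features, is.null, logical(1)))
    if (!has_retest) {
      if (!is.null(attr(cohort, "config"))) {
        cohort <- generate_retest(cohort, rho = config$retest_rho,
                                  seed = seed + 2000L)
      } else {
        stop("pipeline stage 'retest': cohort has no retest session and is ",
             "not synthetic (cannot generate one)", call. = FALSE)
      }
    }
    res <- run_test_retest(cohort, config$models, config$densities)
    add(res$records, "retest_records.csv")
    add(res$summary, "retest_summary.csv")
    message(sprintf("[retest] %d record rows", nrow(res$records)))
  }

  if ("group" %in% config$analyses) {
    res <- run_subject_vs_group(cohort, config$models, config$densities)
    add(res$records, "group_records.csv")
    add(res$summary, "group_summary.csv")
    for (m in names(res$group_networks)) {
      for (d in names(res$group_networks[[m]])) {
        p <- file.path(out, sprintf("group_%s_%s.tsv", m, d))
        write_msn(res$group_networks[[m]][[d]]$weights, p)
        written <<- c(written, p)
      }
    }
    message(sprintf("[group] %d record rows", nrow(res$records)))
  }

  if ("predict" %in% config$analyses) {
    pr <- config$predict
    y <- if (pr$outcome == "ef") {
      ef_summary(as.matrix(cohort[c("ef1", "ef2", "ef3")]))$scores
    } else {
      cohort$cog_comp
    }
    metric <- nodal_metric_matrix(cohort, pr$model, pr$density, pr$metric)
    Xr <- residualize_confounds(metric, cohort$age, cohort$sex)
    sel <- pls_cv_select(Xr, y, c_max = pr$c_max,
                         n_instances = pr$instances, k = pr$folds,
                         seed = seed + 3000L, stratified = pr$stratified,
                         n_bins = pr$n_bins)
    add(sel$selection_counts, "pls_selection_counts.csv")
    add(sel$q2_curves, "pls_q2_curves.csv")
    add(glance(sel), "pls_glance.csv")
    if (sel$chosen_c > 0) {
      bw <- bootstrap_weights(Xr, y, sel$chosen_c, n_boot = pr$n_boot,
                              seed = seed + 4000L)
      add(bw, "pls_weights.csv")
      message(sprintf("[predict] chosen_c = %d, weights bootstrapped",
                      sel$chosen_c))
    } else {
      message("[predict] chosen_c = 0: no model built")
    }
  }

  manifest <- tibble::tibble(
    file = basename(written),
    rows = vapply(written, function(p) {
      if (endsWith(p, ".csv")) {
        nrow(readr::read_csv(p, comment = "#", show_col_types = FALSE))
      } else {
        length(readLines(p)) - 1L
      }
    }, integer(1), USE.NAMES = FALSE),
    md5 = unname(tools::md5sum(written))
  )
  readr::write_csv(manifest, file.path(out, "manifest.csv"))
  invisible(manifest)
}
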