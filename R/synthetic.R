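# Latent-factor synthetic cohort generator: parcellated morphometry with
# shared cross-subject covariance, modality-grouped noise, retest sessions
# with tunable reliability, and cognitive scores with tunable coupling to
# network topology.

.default_feature_scales <- function(features) {
  # native-unit scale/offset pairs emulating the order-of-magnitude spread of
  # raw morphometrics (volume ~10^3 mm^3, diffusivity ~10^-3 mm^2/s, ...)
  all <- list(
    CT   = c(scale = 0.25,    offset = 2.5),     # mm
    SA   = c(scale = 150,     offset = 700),     # mm^2
    GM   = c(scale = 500,     offset = 3000),    # mm^3
    MC   = c(scale = 0.03,    offset = 0.13),    # mm^-1
    GC   = c(scale = 0.06,    offset = 0.22),    # mm^-2
    FI   = c(scale = 0.8,     offset = 3),
    CI   = c(scale = 0.6,     offset = 2.5),
    T1T2 = c(scale = 0.15,    offset = 1.6),
    FA   = c(scale = 0.06,    offset = 0.45),
    MD   = c(scale = 1.2e-4,  offset = 8e-4)     # mm^2/s
  )
  absent <- setdiff(features, names(all))
  if (length(absent) > 0) {
    extra <- stats::setNames(rep(list(c(scale = 1, offset = 0)),
                                 length(absent)), absent)
    all <- c(all, extra)
  }
  all[features]
}

#' Configuration for a synthetic morphometry cohort
#'
#' Defines the generative model: a cohort-level latent loading structure
#' shared by all subjects (producing high subject-to-group-mean similarity),
#' subject-specific deviations, modality-grouped noise components (features
#' within an MRI modality share a noise component, so dropping a modality
#' removes real subject-specific information — this is what makes the
#' 10- vs 8- vs 7-feature hierarchy non-trivial), and per-feature affine
#' rescaling into native units spanning several orders of magnitude.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param n_regions Number of cortical regions (default 68, the
#'   Desikan-Killiany atlas).
#' @param feature_spec A [feature_set()] (default `msn10`).
#' @param n_latent Latent dimensions driving shared regional structure.
#' @param modality_noise Named numeric: noise SD per modality on the
#'   standardized latent scale (all >= 0).
#' @param subject_sd SD of subject-specific cell-wise deviations (>= 0).
#' @param scale_vector Named list feature -> `c(scale, offset)` affine
#'   rescaling into native units; defaults emulate FreeSurfer-scale values.
#' @param retest_reliability Default test-retest reliability rho in \[0, 1\]
#'   used by [generate_retest()] when no rho is given.
#' @param behavior_effect Coupling beta (>= 0) of the cognitive composite to
#'   network topology; 0 (the default) makes cognition independent of the
#'   networks.
#' @param age_range Two-element numeric, years; ages drawn uniformly.
#' @param seed Integer seed; the whole cohort is a deterministic function of
#'   the configuration.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_subjects = 50,
                          n_regions = 68,
                          feature_spec = feature_set("msn10"),
                          n_latent = 5,
                          modality_noise = c(T1w = 0.4, T2w = 0.6, DWI = 0.6),
                          subject_sd = 0.3,
                          scale_vector = NULL,
                          retest_reliability = 0.8,
                          behavior_effect = 0,
                          age_range = c(22, 36),
                          seed = 1L) {
  feature_spec <- .as_feature_set(feature_spec)
  if (is.null(scale_vector)) {
    scale_vector <- .default_feature_scales(feature_spec$features)
  }
  cfg <- structure(
    list(n_subjects = n_subjects, n_regions = n_regions,
         feature_spec = feature_spec, n_latent = n_latent,
         modality_noise = modality_noise, subject_sd = subject_sd,
         scale_vector = scale_vector,
         retest_reliability = retest_reliability,
         behavior_effect = behavior_effect,
         age_range = age_range, seed = as.integer(seed)),
    class = "cohort_config"
  )
  .validate_cohort_config(cfg)
  cfg
}

.validate_cohort_config <- function(cfg) {
  bad <- function(field, why) {
    stop("invalid cohort configuration: `", field, "` ", why, call. = FALSE)
  }
  if (!is.numeric(cfg$n_subjects) || cfg$n_subjects < 2) bad("n_subjects", "must be >= 2")
  if (!is.numeric(cfg$n_regions) || cfg$n_regions < 3) bad("n_regions", "must be >= 3")
  if (!is.numeric(cfg$n_latent) || cfg$n_latent < 1) bad("n_latent", "must be >= 1")
  if (any(cfg$modality_noise < 0)) bad("modality_noise", "must be >= 0")
  mods <- unique(unname(cfg$feature_spec$modality_of))
  if (!all(mods %in% names(cfg$modality_noise))) {
    bad("modality_noise", paste("must name every modality:",
                                paste(mods, collapse = ", ")))
  }
  if (cfg$subject_sd < 0) bad("subject_sd", "must be >= 0")
  if (cfg$retest_reliability < 0 || cfg$retest_reliability > 1) {
    bad("retest_reliability", "must be in [0, 1]")
  }
  if (cfg$behavior_effect < 0) bad("behavior_effect", "must be >= 0")
  if (!setequal(names(cfg$scale_vector), cfg$feature_spec$features)) {
    bad("scale_vector", "must have one entry per feature in feature_spec")
  }
  invisible(cfg)
}

#' Generate a synthetic morphometry cohort
#'
#' Draws, per cohort, a shared regional loading matrix (n_regions x
#' n_latent) and per-feature latent weights whose product is the group-mean
#' standardized feature matrix; each subject then adds cell-wise Gaussian
#' deviations (SD `subject_sd`) and modality-shared noise components, and
#' every feature is affinely rescaled into native units. Covariates (age,
#' sex) and cognitive scores (via [generate_cognition()] with
#' `behavior_effect`) are generated alongside. Regenerating with the same
#' configuration reproduces the cohort bit-identically.
#'
#' @param config A [cohort_config()].
#' @return An `msn_cohort`: a tibble with one row per subject
#'   (`subject_id`, `age`, `sex`, `cog_comp`, `ef1`-`ef3`, list-column
#'   `features` of region x feature tibbles, list-column `retest_features`
#'   initially `NULL`), carrying the generative internals as attributes so
#'   retest sessions and cognition can be regenerated consistently.
#' @export
generate_cohort <- function(config) {
  .validate_cohort_config(config)
  cfg <- config
  atlas <- dk_atlas(cfg$n_regions)
  feats <- cfg$feature_spec$features
  p <- length(feats)
  n <- cfg$n_subjects

  state <- withr::with_seed(cfg$seed, {
    L <- matrix(stats::rnorm(cfg$n_regions * cfg$n_latent),
                cfg$n_regions, cfg$n_latent)
    V <- matrix(stats::rnorm(cfg$n_latent * p), cfg$n_latent, p)
    signal <- (L %*% V) / sqrt(cfg$n_latent)
    colnames(signal) <- feats
    rownames(signal) <- atlas
    noise <- lapply(seq_len(n), function(s) .draw_session_noise(cfg, atlas))
    age <- stats::runif(n, cfg$age_range[1], cfg$age_range[2])
    sex <- sample(c("F", "M"), n, replace = TRUE)
    list(signal = signal, noise = noise, age = age, sex = sex)
  })

  features <- lapply(state$noise, function(E) {
    .to_native_units(state$signal + E, cfg, atlas)
  })

  cohort <- tibble::tibble(
    subject_id = sprintf("sub%04d", seq_len(n)),
    age = state$age,
    sex = state$sex,
    cog_comp = NA_real_,
    ef1 = NA_real_, ef2 = NA_real_, ef3 = NA_real_,
    features = features,
    retest_features = vector("list", n)
  )
  attr(cohort, "config") <- cfg
  attr(cohort, "signal") <- state$signal
  attr(cohort, "noise") <- state$noise
  class(cohort) <- c("msn_cohort", class(cohort))
  generate_cognition(cohort, beta = cfg$behavior_effect,
                     seed = cfg$seed + 101L)
}

# One session's random part on the latent scale: cell-wise subject deviation
# plus a per-modality regional component shared by that modality's features.
.draw_session_noise <- function(cfg, atlas) {
  feats <- cfg$feature_spec$features
  E <- matrix(stats::rnorm(cfg$n_regions * length(feats), sd = cfg$subject_sd),
              cfg$n_regions, length(feats), dimnames = list(atlas, feats))
  mods <- unique(unname(cfg$feature_spec$modality_of))
  for (m in mods) {
    u <- stats::rnorm(cfg$n_regions)
    in_mod <- feats[cfg$feature_spec$modality_of == m]
    E[, in_mod] <- E[, in_mod] + cfg$modality_noise[[m]] * u
  }
  E
}

.to_native_units <- function(Z, cfg, atlas) {
  feats <- cfg$feature_spec$features
  X <- Z
  for (f in feats) {
    sv <- cfg$scale_vector[[f]]
    X[, f] <- sv[["offset"]] + sv[["scale"]] * Z[, f]
  }
  tibble::add_column(tibble::as_tibble(X), region = atlas, .before = 1L)
}

#' Add a retest session with a target test-retest reliability
#'
#' Builds the second-session feature tables as the cohort-level signal plus a
#' rho-weighted mixture of the subject's session-1 random part and a fresh
#' draw with the same covariance structure:
#' `noise2 = rho * noise1 + sqrt(1 - rho^2) * fresh`. The population
#' correlation of every (region, feature) cell across sessions therefore
#' equals `rho`; `rho = 1` reproduces session 1 exactly and `rho = 0` gives
#' an independent session.
#'
#' @param cohort An `msn_cohort` from [generate_cohort()].
#' @param rho Target reliability in \[0, 1\]; defaults to the configuration's
#'   `retest_reliability`.
#' @param seed Integer seed (default derived from the cohort seed).
#' @return The cohort with the `retest_features` list-column filled.
#' @export
generate_retest <- function(cohort, rho = NULL, seed = NULL) {
  cfg <- attr(cohort, "config")
  if (is.null(cfg)) stop("not a generated msn_cohort", call. = FALSE)
  if (is.null(rho)) rho <- cfg$retest_reliability
  if (!is.numeric(rho) || rho < 0 || rho > 1) {
    stop("retest reliability rho must be in [0, 1]", call. = FALSE)
  }
  if (is.null(seed)) seed <- cfg$seed + 211L
  atlas <- dk_atlas(cfg$n_regions)
  signal <- attr(cohort, "signal")
  noise1 <- attr(cohort, "noise")
  retest <- withr::with_seed(seed, {
    lapply(noise1, function(E1) {
      E2 <- rho * E1 + sqrt(1 - rho^2) * .draw_session_noise(cfg, atlas)
      .to_native_units(signal + E2, cfg, atlas)
    })
  })
  cohort$retest_features <- retest
  cohort
}

#' Generate cognitive scores coupled to network topology
#'
#' The cognitive composite is
#' `cog_comp = beta * z(contrast %*% strength_s) + N(0, noise_sd)`, where
#' `strength_s` is subject s's full-density MSN nodal-strength profile and
#' the contrast is a fixed random direction drawn from the seed; `beta = 0`
#' yields cognition independent of every network measure. The three
#' executive-function subtests load 0.8 each on a single latent EF factor
#' (itself coupled to the same network projection through `beta`) plus
#' independent noise, so their correlation matrix is compound-symmetric with
#' a dominant first principal component.
#'
#' @param cohort An `msn_cohort`.
#' @param beta Coupling strength (>= 0).
#' @param noise_sd SD of the additive score noise.
#' @param ef_loading Loading of each EF subtest on the latent EF factor.
#' @param seed Integer seed.
#' @return The cohort with `cog_comp` and `ef1`-`ef3` filled; the per-subject
#'   nodal-strength matrix and the contrast are attached as attributes
#'   `true_strength` and `contrast` for oracle checks.
#' @export
generate_cognition <- function(cohort, beta = 0, noise_sd = 1,
                               ef_loading = 0.8, seed = NULL) {
  cfg <- attr(cohort, "config")
  if (is.null(cfg)) stop("not a generated msn_cohort", call. = FALSE)
  if (!is.numeric(beta) || beta < 0) stop("beta must be >= 0", call. = FALSE)
  if (is.null(seed)) seed <- cfg$seed + 307L
  strength <- t(vapply(cohort$features,
                       function(ft) nodal_strength(build_msn(ft)),
                       numeric(cfg$n_regions)))
  n <- nrow(cohort)
  scores <- withr::with_seed(seed, {
    contrast <- stats::rnorm(cfg$n_regions)
    proj <- as.numeric(strength %*% contrast)
    zproj <- if (stats::sd(proj) > 0) as.numeric(scale(proj)) else proj * 0
    cog <- beta * zproj + stats::rnorm(n, sd = noise_sd)
    g <- beta * zproj + stats::rnorm(n, sd = noise_sd)
    g <- if (stats::sd(g) > 0) as.numeric(scale(g)) else g
    resid_sd <- sqrt(max(0, 1 - ef_loading^2))
    ef <- vapply(1:3, function(j) ef_loading * g + stats::rnorm(n, sd = resid_sd),
                 numeric(n))
    list(cog = cog, ef = ef, contrast = contrast)
  })
  cohort$cog_comp <- scores$cog
  cohort$ef1 <- scores$ef[, 1]
  cohort$ef2 <- scores$ef[, 2]
  cohort$ef3 <- scores$ef[, 3]
  attr(cohort, "true_strength") <- strength
  attr(cohort, "contrast") <- scores$contrast
  cohort
}

#' Write a cohort to disk
#'
#' One TSV feature table per subject per session
#' (`<subject>_<session>.tsv`, regions as rows), a cohort-level
#' `covariates.csv` (subject_id, session, age, sex, cog_comp, ef1-ef3) and
#' the configuration as `config.yaml`.
#'
#' @param cohort An `msn_cohort`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- attr(cohort, "config")
  has_retest <- !vapply(cohort$retest_features, is.null, logical(1))
  for (i in seq_len(nrow(cohort))) {
    write_feature_table(cohort$features[[i]],
                        file.path(dir, paste0(cohort$subject_id[i], "_test.tsv")))
    if (has_retest[i]) {
      write_feature_table(cohort$retest_features[[i]],
                          file.path(dir, paste0(cohort$subject_id[i], "_retest.tsv")))
    }
  }
  cov <- cohort[c("subject_id", "age", "sex", "cog_comp", "ef1", "ef2", "ef3")]
  cov <- tibble::add_column(tibble::as_tibble(cov),
                            session = ifelse(has_retest, "test+retest", "test"),
                            .after = "subject_id")
  readr::write_csv(cov, file.path(dir, "covariates.csv"))
  if (!is.null(cfg)) {
    yaml::write_yaml(
      list(n_subjects = cfg$n_subjects, n_regions = cfg$n_regions,
           feature_set = cfg$feature_spec$name, n_latent = cfg$n_latent,
           modality_noise = as.list(cfg$modality_noise),
           subject_sd = cfg$subject_sd,
           retest_reliability = cfg$retest_reliability,
           behavior_effect = cfg$behavior_effect,
           age_range = cfg$age_range, seed = cfg$seed),
      file.path(dir, "config.yaml")
    )
  }
  invisible(dir)
}

#' Read a cohort from disk
#'
#' Reassembles an `msn_cohort` tibble from a directory written by
#' [write_cohort()] (or assembled by hand in the same layout).
#'
#' @param dir Directory containing `<subject>_<session>.tsv` tables and
#'   `covariates.csv`.
#' @param atlas Region atlas (default inferred from the first table's rows
#'   via [dk_atlas()] with 68 regions).
#' @param spec Feature set to retain (default `msn10`).
#' @return An `msn_cohort` tibble (without generative attributes).
#' @export
read_cohort <- function(dir, atlas = dk_atlas(), spec = feature_set("msn10")) {
  cov <- read_covariates(file.path(dir, "covariates.csv"))
  features <- lapply(cov$subject_id, function(id) {
    read_feature_table(file.path(dir, paste0(id, "_test.tsv")), atlas, spec)
  })
  retest <- lapply(cov$subject_id, function(id) {
    p <- file.path(dir, paste0(id, "_retest.tsv"))
    if (file.exists(p)) read_feature_table(p, atlas, spec) else NULL
  })
  cohort <- tibble::tibble(
    subject_id = cov$subject_id, age = cov$age, sex = cov$sex,
    cog_comp = cov$cog_comp, ef1 = cov$ef1, ef2 = cov$ef2, ef3 = cov$ef3,
    features = features, retest_features = retest
  )
  class(cohort) <- c("msn_cohort", class(cohort))
  cohort
}
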