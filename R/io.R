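# Reading, validating and writing region-by-feature morphometry tables.

#' Read a parcellated morphometry table
#'
#' Reads a per-subject region-by-feature table (tab- or comma-separated,
#' auto-detected) and normalizes it to the canonical layout: one row per
#' atlas region in atlas order, one column per feature of the requested
#' feature set, values left in native units. Two dialects are accepted:
#'
#' * long — a region-label column (first column) and one column per feature,
#'   the natural layout of per-region exports;
#' * wide — a single data row with columns named `<region>_<feature>`, the
#'   layout emitted by FreeSurfer's `aparcstats2table`.
#'
#' Region labels are matched case-insensitively with `-`/`_`/`.` separators
#' ignored, so `lh-bankssts`, `lh_bankssts` and `LH_BANKSSTS` are the same
#' region. Rows whose label matches no atlas region (e.g. subcortical
#' structures) are dropped with a warning.
#'
#' @param path Path to the delimited text file.
#' @param atlas Character vector of region labels defining row order
#'   (default [dk_atlas()]).
#' @param spec A [feature_set()] (or its name) naming the features to retain.
#' @return A `feature_table`: a tibble with a `region` column followed by one
#'   numeric column per feature, rows in atlas order.
#' @export
read_feature_table <- function(path, atlas = dk_atlas(), spec = feature_set("msn10")) {
  spec <- .as_feature_set(spec)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = delim,
                           check.names = FALSE, stringsAsFactors = FALSE)
  atlas_norm <- .normalize_label(atlas)

  first_col <- as.character(raw[[1L]])
  if (any(.normalize_label(first_col) %in% atlas_norm)) {
    tbl <- .parse_long_table(raw, atlas, atlas_norm, spec, path)
  } else {
    tbl <- .parse_wide_table(raw, atlas, atlas_norm, spec, path)
  }
  .validate_feature_table(tbl, atlas, spec, path)
  tbl
}

.parse_long_table <- function(raw, atlas, atlas_norm, spec, path) {
  labels_norm <- .normalize_label(as.character(raw[[1L]]))
  known <- labels_norm %in% atlas_norm
  if (any(!known)) {
    warning("dropping ", sum(!known), " non-atlas row(s): ",
            paste(utils::head(raw[[1L]][!known], 5L), collapse = ", "),
            call. = FALSE)
    raw <- raw[known, , drop = FALSE]
    labels_norm <- labels_norm[known]
  }
  missing_regions <- atlas[!(atlas_norm %in% labels_norm)]
  if (length(missing_regions) > 0) {
    stop("missing region(s): ", paste(missing_regions, collapse = ", "),
         call. = FALSE)
  }
  cols_norm <- toupper(gsub("[-_.]", "", names(raw)))
  idx <- match(toupper(spec$features), cols_norm)
  if (anyNA(idx)) {
    stop("missing feature column(s): ",
         paste(spec$features[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  vals <- raw[idx]
  for (j in seq_along(vals)) {
    v <- suppressWarnings(as.numeric(vals[[j]]))
    bad <- which(is.na(v) & !is.na(vals[[j]]))
    if (length(bad) > 0 || anyNA(vals[[j]])) {
      row_bad <- if (length(bad) > 0) bad[1L] else which(is.na(vals[[j]]))[1L]
      stop(sprintf("non-numeric or missing cell in %s at row %d, column '%s'",
                   path, row_bad, spec$features[j]), call. = FALSE)
    }
    vals[[j]] <- v
  }
  names(vals) <- spec$features
  ord <- match(atlas_norm, labels_norm)
  tibble::as_tibble(c(list(region = atlas), vals[ord, , drop = FALSE]))
}

.parse_wide_table <- function(raw, atlas, atlas_norm, spec, path) {
  if (nrow(raw) != 1L) {
    stop("cannot interpret ", path, ": no region-label column and not a ",
         "single-row wide table", call. = FALSE)
  }
  # drop a leading subject-id column if non-numeric
  if (!is.numeric(raw[[1L]])) raw <- raw[-1L]
  cols <- names(raw)
  cols_norm <- .normalize_label(cols)
  mat <- matrix(NA_real_, length(atlas), length(spec$features),
                dimnames = list(atlas, spec$features))
  for (k in seq_along(cols)) {
    for (f in spec$features) {
      suffix <- .normalize_label(f)
      if (endsWith(cols_norm[k], suffix)) {
        region_part <- substr(cols_norm[k], 1L,
                              nchar(cols_norm[k]) - nchar(suffix))
        i <- match(region_part, atlas_norm)
        if (!is.na(i)) {
          v <- suppressWarnings(as.numeric(raw[[k]]))
          if (is.na(v)) {
            stop(sprintf("non-numeric cell in %s, column '%s'", path, cols[k]),
                 call. = FALSE)
          }
          mat[i, f] <- v
        }
      }
    }
  }
  missing_regions <- atlas[rowSums(is.na(mat)) == ncol(mat)]
  if (length(missing_regions) > 0) {
    stop("missing region(s): ", paste(missing_regions, collapse = ", "),
         call. = FALSE)
  }
  missing_feats <- spec$features[colSums(is.na(mat)) > 0]
  if (length(missing_feats) > 0) {
    stop("missing feature column(s): ", paste(missing_feats, collapse = ", "),
         call. = FALSE)
  }
  tibble::as_tibble(cbind(tibble::tibble(region = atlas),
                          tibble::as_tibble(mat)))
}

.validate_feature_table <- function(tbl, atlas, spec, what = "feature table") {
  stopifnot(identical(tbl$region, atlas))
  vals <- as.matrix(tbl[spec$features])
  if (!all(is.finite(vals))) {
    stop("non-finite values in ", what, call. = FALSE)
  }
  invisible(tbl)
}

#' Write a feature table to canonical TSV
#'
#' Writes the canonical per-subject layout: regions as rows in atlas order,
#' the region label in the first column, one column per feature, tab
#' separated. [read_feature_table()] of the result is lossless for finite
#' values at the written precision (full double precision is used).
#'
#' @param table A `feature_table` tibble as returned by
#'   [read_feature_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  out <- table
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Subset a feature table to a nested feature model
#'
#' Selects the columns of a reduced feature model from a fuller table,
#' preserving the requested feature order. This is how the 8- and 7-feature
#' model inputs are derived from the full 10-feature table.
#'
#' @param table A `feature_table` tibble.
#' @param spec Target [feature_set()] (or its name); its features must all be
#'   present in `table`.
#' @return The column-subset tibble (`region` plus the requested features).
#' @export
#' @examples
#' \dontrun{
#' msn7_tbl <- subset_features(msn10_tbl, "msn7")
#' }
subset_features <- function(table, spec) {
  spec <- .as_feature_set(spec)
  absent <- setdiff(spec$features, names(table))
  if (length(absent) > 0) {
    stop("feature(s) absent from table: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  table[c("region", spec$features)]
}

#' Read a cohort covariates table
#'
#' Reads the cohort-level covariates CSV written by [write_cohort()]:
#' one row per subject with `subject_id`, `age` (years), `sex` (`F`/`M`),
#' `cog_comp` and the three executive-function subtest scores
#' `ef1`, `ef2`, `ef3`.
#'
#' @param path Path to the CSV file.
#' @return A tibble of covariates.
#' @export
read_covariates <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
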