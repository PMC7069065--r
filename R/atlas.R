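# Region atlas and nested feature-set definitions.

.dk_base_labels <- c(
  "bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus",
  "entorhinal", "fusiform", "inferiorparietal", "inferiortemporal",
  "isthmuscingulate", "lateraloccipital", "lateralorbitofrontal", "lingual",
  "medialorbitofrontal", "middletemporal", "parahippocampal", "paracentral",
  "parsopercularis", "parsorbitalis", "parstriangularis", "pericalcarine",
  "postcentral", "posteriorcingulate", "precentral", "precuneus",
  "rostralanteriorcingulate", "rostralmiddlefrontal", "superiorfrontal",
  "superiorparietal", "superiortemporal", "supramarginal", "frontalpole",
  "temporalpole", "transversetemporal", "insula"
)

#' Desikan-Killiany cortical atlas labels
#'
#' The fixed region ordering used throughout the package: the 68 cortical
#' Desikan-Killiany parcels, 34 per hemisphere, left hemisphere first.
#' All feature tables are normalized to this order on read, so matrices from
#' different subjects, sessions and feature models are always node-aligned.
#'
#' @param n_regions Number of regions. The default 68 returns the
#'   Desikan-Killiany labels; any other value returns generic labels
#'   (`region_01`, ...) for reduced test fixtures.
#' @return Character vector of unique, ordered region labels.
#' @export
#' @examples
#' head(dk_atlas())
#' length(dk_atlas())
dk_atlas <- function(n_regions = 68) {
  if (n_regions == 68) {
    c(paste0("lh_", .dk_base_labels), paste0("rh_", .dk_base_labels))
  } else {
    if (n_regions < 3) stop("n_regions must be >= 3", call. = FALSE)
    sprintf("region_%02d", seq_len(n_regions))
  }
}

# canonical form used for matching: lowercase, separators stripped
.normalize_label <- function(x) gsub("[-_.]", "", tolower(x))

.msn_feature_modality <- c(
  CT = "T1w", SA = "T1w", GM = "T1w", MC = "T1w", GC = "T1w",
  FI = "T1w", CI = "T1w", T1T2 = "T2w", FA = "DWI", MD = "DWI"
)

#' Nested MSN feature-set specifications
#'
#' The three hierarchically nested feature models used for network
#' construction:
#' * `msn10` — all ten features: seven T1w-derived morphometrics (cortical
#'   thickness CT, surface area SA, gray-matter volume GM, mean curvature MC,
#'   Gaussian curvature GC, folding index FI, curvature index CI), the
#'   T1w/T2w ratio (myelin proxy) and the two diffusion metrics (fractional
#'   anisotropy FA, mean diffusivity MD);
#' * `msn8` — `msn10` without FA and MD (no diffusion acquisition);
#' * `msn7` — `msn8` without the T1w/T2w ratio (T1w acquisition only).
#'
#' @param name One of `"msn10"`, `"msn8"`, `"msn7"`.
#' @return An object of class `feature_set`: a list with `name`, `features`
#'   (ordered character vector of feature codes) and `modality_of` (named map
#'   feature -> modality in `{T1w, T2w, DWI}`).
#' @export
#' @examples
#' feature_set("msn7")$features
feature_set <- function(name = c("msn10", "msn8", "msn7")) {
  name <- match.arg(name)
  features <- switch(name,
    msn10 = names(.msn_feature_modality),
    msn8  = setdiff(names(.msn_feature_modality), c("FA", "MD")),
    msn7  = setdiff(names(.msn_feature_modality), c("FA", "MD", "T1T2"))
  )
  structure(
    list(
      name = name,
      features = features,
      modality_of = .msn_feature_modality[features]
    ),
    class = "feature_set"
  )
}

#' @export
print.feature_set <- function(x, ...) {
  cat("<feature_set> ", x$name, ": ", paste(x$features, collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

.as_feature_set <- function(spec) {
  if (inherits(spec, "feature_set")) return(spec)
  if (is.character(spec) && length(spec) == 1) return(feature_set(spec))
  stop("`spec` must be a feature_set or one of 'msn10', 'msn8', 'msn7'",
       call. = FALSE)
}
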