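# Delta features and the seven pre/post/delta feature combinations.

#' Extract the full feature vector of one ROI scan
#'
#' Concatenates intensity, GLCM texture, and geometry features. The
#' realized catalogue size depends on the GLCM settings; the default
#' (32 levels, distances 1/2/4, 4 angle-averaged angles) yields
#' 9 + 36 + 8 = 53 features per examination.
#'
#' @param scan a [roi_scan()].
#' @param settings GLCM settings, see [glcm_settings()].
#' @param strict raise degenerate-ROI errors (default `TRUE`).
#' @return named numeric vector.
#' @export
extract_features <- function(scan, settings = glcm_settings(), strict = TRUE) {
  c(intensity_features(scan, strict = strict),
    glcm_texture_features(scan, settings, strict = strict),
    geometry_features(scan))
}

#' Names of the full feature catalogue
#'
#' @param settings GLCM settings.
#' @return character vector of feature names (unprefixed).
#' @export
feature_catalogue <- function(settings = glcm_settings()) {
  c("minimum", "maximum", "mean", "stand_deviation", "sum", "median",
    "skewness", "kurtosis", "variance",
    as.vector(t(outer(glcm_stat_names, settings$distances,
                      function(s, d) paste0(s, "_d", d)))),
    c("volume", "major_diameter", "minor_diameter", "eccentricity",
      "elongation", "orientation", "bounding_box_volume", "perimeter"))
}

#' Delta features: post minus pre
#'
#' @param pre,post named feature vectors over identical name sets, from
#'   the baseline and post-cycle-1 examinations. Vectors carrying a
#'   `provenance` attribute of `"delta"` are rejected (a delta of deltas
#'   is undefined).
#' @return named vector `post - pre`, with `provenance` `"delta"`.
#' @export
delta_features <- function(pre, post) {
  if (identical(attr(pre, "provenance"), "delta") ||
      identical(attr(post, "provenance"), "delta"))
    rader_abort("delta of delta features is undefined", "catalogue")
  if (!setequal(names(pre), names(post)) ||
      length(pre) != length(post))
    rader_abort("pre/post feature name sets differ", "catalogue")
  d <- post[names(pre)] - pre
  attr(d, "provenance") <- "delta"
  d
}

#' The seven feature combinations, in reporting order
#'
#' @return character vector of combination ids.
#' @export
combination_names <- function() {
  c("pre", "pre+delta", "post", "post+delta", "pre+post", "pre+post+delta",
    "delta")
}

combination_parts <- function(combo) {
  parts <- strsplit(combo, "+", fixed = TRUE)[[1]]
  if (!combo %in% combination_names())
    rader_abort(paste0("unknown combination '", combo, "'; one of: ",
                       paste(combination_names(), collapse = ", ")), "config")
  parts
}

#' Assemble one of the seven pre/post/delta combinations
#'
#' Column-concatenates the requested provenance matrices; columns are
#' prefixed `pre_`/`post_`/`delta_`. Matrices must be row-aligned by
#' patient.
#'
#' @param tables named list with elements `pre`, `post`, `delta`, each a
#'   [feature_matrix()] over the same patients.
#' @param combo one of [combination_names()].
#' @return feature matrix.
#' @export
assemble_combination <- function(tables, combo) {
  parts <- combination_parts(combo)
  pieces <- lapply(parts, function(p) {
    fm <- tables[[p]]
    if (is.null(fm)) rader_abort(paste0("missing provenance table '", p, "'"),
                                 "cohort")
    cn <- colnames(fm$x)
    pref <- paste0(p, "_")
    if (length(cn) && !all(startsWith(cn, pref))) {
      fm2 <- fm
      colnames(fm2$x) <- paste0(pref, cn)
      fm2
    } else fm
  })
  do.call(fm_cbind, pieces)
}

#' Extract pre/post/delta feature tables for a cohort
#'
#' Runs the extractor on every patient's pre and post scans, forms delta
#' features, and returns the three row-aligned feature matrices with
#' provenance-prefixed column names. Patients with degenerate ROIs
#' (undefined moments) are excluded with a message, mirroring a clinical
#' exclusion list.
#'
#' @param patients list of synthetic or loaded patients; each element
#'   needs `patient_id`, `pre_scan`, `post_scan`, `label`, and
#'   optionally `arm`.
#' @param settings GLCM settings.
#' @return named list `pre`, `post`, `delta` of feature matrices, plus
#'   `excluded` (character ids).
#' @export
extract_cohort_features <- function(patients, settings = glcm_settings()) {
  rows_pre <- list(); rows_post <- list(); rows_delta <- list()
  ids <- character(0); labels <- character(0); arms <- character(0)
  excluded <- character(0)
  for (p in patients) {
    fp <- tryCatch(extract_features(p$pre_scan, settings),
                   rader_error_degenerate_roi = function(e) NULL)
    fq <- tryCatch(extract_features(p$post_scan, settings),
                   rader_error_degenerate_roi = function(e) NULL)
    if (is.null(fp) || is.null(fq)) {
      excluded <- c(excluded, p$patient_id)
      next
    }
    rows_pre[[length(rows_pre) + 1L]] <- fp
    rows_post[[length(rows_post) + 1L]] <- fq
    rows_delta[[length(rows_delta) + 1L]] <- delta_features(fp, fq)
    ids <- c(ids, p$patient_id)
    labels <- c(labels, p$label)
    arms <- c(arms, p$arm %||% NA_character_)
  }
  if (length(excluded))
    message("excluded degenerate ROIs: ", paste(excluded, collapse = ", "))
  arms <- if (all(is.na(arms))) NULL else arms
  as_fm <- function(rows, prefix) {
    x <- do.call(rbind, rows)
    colnames(x) <- paste0(prefix, "_", colnames(x))
    feature_matrix(x, labels, arm = arms, patient_id = ids)
  }
  list(pre = as_fm(rows_pre, "pre"), post = as_fm(rows_post, "post"),
       delta = as_fm(rows_delta, "delta"), excluded = excluded)
}
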