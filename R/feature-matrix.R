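# FeatureMatrix: cohort table of named radiomic features with labels.

#' Construct a feature matrix
#'
#' The cohort-level container used by every downstream stage: a numeric
#' matrix of named features, one row per patient, with a binary response
#' label (`good`/`poor`) and optionally an arm (`train`/`validation`)
#' per row.
#'
#' @param x numeric matrix with unique column names; no missing values.
#' @param label character/factor of `"good"`/`"poor"`, one per row.
#' @param arm optional character/factor of `"train"`/`"validation"`.
#' @param patient_id optional character ids; defaults to rownames or
#'   `P001...`.
#' @return object of class `feature_matrix`.
#' @export
feature_matrix <- function(x, label, arm = NULL, patient_id = NULL) {
  if (!is.matrix(x)) x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(colnames(x)) && ncol(x) > 0)
    rader_abort("feature columns must be named", "format")
  if (anyDuplicated(colnames(x)))
    rader_abort("duplicate feature column names", "format")
  if (nrow(x) > 0 && any(!is.finite(x)))
    rader_abort("feature matrix contains non-finite values", "format")
  label <- as.character(label)
  if (length(label) != nrow(x))
    rader_abort("one label per row required", "format")
  if (nrow(x) > 0 && !all(label %in% c("good", "poor")))
    rader_abort("labels must be 'good' or 'poor'", "format")
  label <- factor(label, levels = c("good", "poor"))
  if (!is.null(arm)) {
    arm <- as.character(arm)
    if (length(arm) != nrow(x))
      rader_abort("one arm per row required", "format")
    if (nrow(x) > 0 && !all(arm %in% c("train", "validation")))
      rader_abort("arm must be 'train' or 'validation'", "format")
    arm <- factor(arm, levels = c("train", "validation"))
  }
  if (is.null(patient_id)) {
    patient_id <- rownames(x) %||% sprintf("P%03d", seq_len(nrow(x)))
  }
  rownames(x) <- patient_id
  structure(list(x = x, label = label, arm = arm,
                 patient_id = as.character(patient_id)),
            class = "feature_matrix")
}

#' @export
dim.feature_matrix <- function(x) dim(x$x)

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d patients x %d features (%d good / %d poor)\n",
              nrow(x$x), ncol(x$x), sum(x$label == "good"),
              sum(x$label == "poor")))
  invisible(x)
}

#' Subset a feature matrix
#'
#' @param fm feature matrix.
#' @param rows,cols index vectors (default: all).
#' @return feature matrix.
#' @export
fm_subset <- function(fm, rows = NULL, cols = NULL) {
  rows <- rows %||% seq_len(nrow(fm$x))
  cols <- cols %||% seq_len(ncol(fm$x))
  feature_matrix(fm$x[rows, cols, drop = FALSE], fm$label[rows],
                 arm = if (!is.null(fm$arm)) fm$arm[rows],
                 patient_id = fm$patient_id[rows])
}

#' Column-bind row-aligned feature matrices
#'
#' @param ... feature matrices over the same patients, in order.
#' @return feature matrix.
#' @export
fm_cbind <- function(...) {
  fms <- list(...)
  base <- fms[[1]]
  for (fm in fms[-1]) {
    if (!identical(fm$patient_id, base$patient_id) ||
        !identical(as.character(fm$label), as.character(base$label)))
      rader_abort("feature matrices are not row-aligned by patient", "cohort")
  }
  feature_matrix(do.call(cbind, lapply(fms, `[[`, "x")), base$label,
                 arm = base$arm, patient_id = base$patient_id)
}

#' Write a feature matrix to CSV
#'
#' Layout: `patient_id`, `arm` (if present), `label`, then one column
#' per feature, written with 17 significant digits so a round-trip is
#' exact to well beyond 12 digits.
#'
#' @param fm feature matrix.
#' @param path output path.
#' @export
write_feature_table <- function(fm, path) {
  df <- data.frame(patient_id = fm$patient_id, stringsAsFactors = FALSE)
  if (!is.null(fm$arm)) df$arm <- as.character(fm$arm)
  df$label <- as.character(fm$label)
  for (j in seq_len(ncol(fm$x)))
    df[[colnames(fm$x)[j]]] <- sprintf("%.17g", fm$x[, j])
  if (nrow(df) == 0) {
    feat <- colnames(fm$x)
    hdr <- c("patient_id", if (!is.null(fm$arm)) "arm", "label", feat)
    writeLines(paste(hdr, collapse = ","), path)
    return(invisible(path))
  }
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a feature matrix from CSV
#'
#' @param path CSV path as written by [write_feature_table()].
#' @return feature matrix.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) rader_abort(paste0("no such file: ", path), "format")
  header <- strsplit(readLines(path, n = 1L), ",")[[1]]
  if (anyDuplicated(header))
    rader_abort(paste0(path, ": duplicate column names"), "format")
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                 colClasses = "character")
  if (!"label" %in% header || !"patient_id" %in% header)
    rader_abort(paste0(path, ": missing patient_id/label columns"), "format")
  meta <- intersect(c("patient_id", "arm", "label"), header)
  feat <- setdiff(header, meta)
  if (nrow(df) > 0 && !all(df$label %in% c("good", "poor")))
    rader_abort(paste0(path, ": label column outside {good, poor}"), "format")
  x <- matrix(0, nrow(df), length(feat), dimnames = list(NULL, feat))
  for (j in seq_along(feat)) {
    v <- suppressWarnings(as.numeric(df[[feat[j]]]))
    if (nrow(df) > 0 && any(is.na(v)))
      rader_abort(paste0(path, ": non-numeric value in column ", feat[j]),
                  "format")
    x[, j] <- v
  }
  feature_matrix(x, label = df$label,
                 arm = if ("arm" %in% header) df$arm,
                 patient_id = df$patient_id)
}
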