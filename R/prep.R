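# Feature normalization and selection: z-scores learned on the training
# arm, Welch t screening, and cross-correlation redundancy removal
# applied separately within the pre / post / delta column groups.

#' Fit z-score parameters on the training arm and apply everywhere
#'
#' Each retained training column is centred and scaled to mean 0,
#' variance 1 (population denominator). Other matrices (e.g. the
#' validation arm) are transformed with the training parameters, never
#' their own. Zero-variance training columns cannot be scaled; they are
#' dropped from every output and recorded in `params$dropped`.
#'
#' @param train training [feature_matrix()] (>= 2 rows).
#' @param ... further matrices to transform with the training
#'   parameters.
#' @return list with `train`, `others` (list), `params`
#'   (`mean`, `sd`, `dropped`).
#' @export
fit_apply_zscore <- function(train, ...) {
  if (nrow(train$x) < 2)
    rader_abort("z-score fitting needs >= 2 training rows", "config")
  mu <- colMeans(train$x)
  sdv <- sqrt(colMeans(sweep(train$x, 2, mu)^2))
  keep <- sdv > 0
  dropped <- colnames(train$x)[!keep]
  params <- list(mean = mu[keep], sd = sdv[keep], dropped = dropped)
  others <- lapply(list(...), apply_zscore, params = params)
  list(train = apply_zscore(train, params), others = others, params = params)
}

#' Apply fitted z-score parameters to a feature matrix
#'
#' @param fm feature matrix containing at least the fitted columns.
#' @param params from [fit_apply_zscore()].
#' @return transformed feature matrix restricted to the fitted columns.
#' @export
apply_zscore <- function(fm, params) {
  cols <- names(params$mean)
  missing <- setdiff(cols, colnames(fm$x))
  if (length(missing))
    rader_abort(paste0("matrix lacks fitted columns: ",
                       paste(missing[1:min(3, length(missing))], collapse = ", ")),
                "format")
  x <- sweep(sweep(fm$x[, cols, drop = FALSE], 2, params$mean), 2, params$sd,
             `/`)
  feature_matrix(x, fm$label, arm = fm$arm, patient_id = fm$patient_id)
}

#' Invert fitted z-score parameters
#'
#' @param fm normalized feature matrix.
#' @param params from [fit_apply_zscore()].
#' @return feature matrix on the original scale.
#' @export
invert_zscore <- function(fm, params) {
  x <- sweep(sweep(fm$x, 2, params$sd, `*`), 2, params$mean, `+`)
  feature_matrix(x, fm$label, arm = fm$arm, patient_id = fm$patient_id)
}

#' Welch two-sample t screening of every feature
#'
#' Tests each column against the good/poor label (two-sided Welch t).
#' Columns with zero variance in both classes get an epsilon-guarded
#' standard error so perfectly separated constant columns yield p -> 0
#' and identical columns p = 1.
#'
#' @param fm feature matrix with both classes present (>= 2 rows each).
#' @return data.frame with `feature`, `t`, `p`.
#' @export
t_screen <- function(fm) {
  g <- fm$label == "good"
  if (sum(g) < 2 || sum(!g) < 2)
    rader_abort("t screening needs >= 2 rows in each class", "class_balance")
  xg <- fm$x[g, , drop = FALSE]
  xp <- fm$x[!g, , drop = FALSE]
  n1 <- nrow(xg); n2 <- nrow(xp)
  m1 <- colMeans(xg); m2 <- colMeans(xp)
  v1 <- apply(xg, 2, var); v2 <- apply(xp, 2, var)
  se2 <- v1 / n1 + v2 / n2
  eps <- .Machine$double.eps * pmax(abs(m1), abs(m2), 1)^2
  se2g <- pmax(se2, eps)
  t <- (m1 - m2) / sqrt(se2g)
  df <- ifelse(se2 > 0,
               se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1)),
               n1 + n2 - 2)
  df[!is.finite(df) | df <= 0] <- n1 + n2 - 2
  p <- 2 * pt(-abs(t), df)
  data.frame(feature = colnames(fm$x), t = as.numeric(t), p = as.numeric(p),
             row.names = NULL, stringsAsFactors = FALSE)
}

provenance_groups <- function(cols) {
  pref <- sub("^(pre|post|delta)_.*$", "\\1", cols)
  pref[!pref %in% c("pre", "post", "delta")] <- "all"
  split(seq_along(cols), pref)
}

#' Cross-correlation redundancy filter
#'
#' Within each provenance group (`pre_`/`post_`/`delta_` column
#' prefixes; unprefixed columns form one group), ranks all column pairs
#' by descending absolute Pearson correlation on the rows it is given
#' (the training arm) and, for every pair still retained whose
#' |correlation| exceeds `threshold`, removes one member until no
#' retained pair exceeds it. With `remove = "less_discriminative"`
#' (default) the member with the larger screening p-value is removed;
#' `remove = "literal"` removes the larger-|t| member instead. Ties
#' break on the later column, deterministically.
#'
#' @param fm training feature matrix.
#' @param screen data.frame from [t_screen()] covering all columns.
#' @param threshold correlation cutoff in (0, 1] (default 0.8).
#' @param remove tie-break rule, see above.
#' @return `selection_result`: list with `retained`, `removed`
#'   (data.frame kept/removed/correlation), `screen`, `threshold`.
#' @export
redundancy_filter <- function(fm, screen = t_screen(fm), threshold = 0.8,
                              remove = c("less_discriminative", "literal")) {
  remove <- match.arg(remove)
  if (!is_number(threshold) || threshold <= 0 || threshold > 1)
    rader_abort("threshold must lie in (0, 1]", "config")
  cols <- colnames(fm$x)
  if (!all(cols %in% screen$feature))
    rader_abort("screen does not cover all columns", "config")
  pvals <- setNames(screen$p, screen$feature)[cols]
  tvals <- setNames(abs(screen$t), screen$feature)[cols]
  retained <- rep(TRUE, length(cols))
  removed <- list()
  for (grp in provenance_groups(cols)) {
    if (length(grp) < 2) next
    cm <- suppressWarnings(cor(fm$x[, grp, drop = FALSE]))
    cm[!is.finite(cm)] <- 0
    pairs <- which(upper.tri(cm) & abs(cm) > threshold, arr.ind = TRUE)
    if (nrow(pairs) == 0) next
    ord <- order(-abs(cm[pairs]))
    pairs <- pairs[ord, , drop = FALSE]
    for (k in seq_len(nrow(pairs))) {
      i <- grp[pairs[k, 1]]; j <- grp[pairs[k, 2]]
      if (!retained[i] || !retained[j]) next
      drop_j <- if (remove == "less_discriminative") {
        pvals[j] > pvals[i] || (pvals[j] == pvals[i])
      } else {
        tvals[j] > tvals[i] || (tvals[j] == tvals[i])
      }
      victim <- if (drop_j) j else i
      keeper <- if (drop_j) i else j
      retained[victim] <- FALSE
      removed[[length(removed) + 1L]] <-
        data.frame(kept = cols[keeper], removed = cols[victim],
                   correlation = cm[pairs[k, 1], pairs[k, 2]],
                   stringsAsFactors = FALSE)
    }
  }
  structure(list(
    retained = cols[retained],
    removed = if (length(removed)) do.call(rbind, removed)
              else data.frame(kept = character(0), removed = character(0),
                              correlation = numeric(0)),
    screen = screen, threshold = threshold
  ), class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %d retained, %d removed (|r| > %.2f)\n",
              length(x$retained), nrow(x$removed), x$threshold))
  invisible(x)
}
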