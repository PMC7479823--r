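# Confusion-matrix metrics, ROC/AUC, and the seven-combination
# comparison report.

#' Confusion counts (positive class = good response)
#'
#' @param tp,fn,fp,tn non-negative integers.
#' @param subgroups optional named list with per-cell subgroup
#'   breakdowns (e.g. predicted-good actual-good split into
#'   pseudoprogression / sd_pr).
#' @return object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, fn, fp, tn, subgroups = NULL) {
  for (v in c(tp, fn, fp, tn))
    if (!is_count(v)) rader_abort("counts must be non-negative integers",
                                  "metric")
  structure(list(tp = tp, fn = fn, fp = fp, tn = tn, subgroups = subgroups),
            class = "confusion_counts")
}

#' Confusion counts from a subgroup table
#'
#' Rows are predicted labels (`good`, `poor`); columns are the clinical
#' subgroups `pseudoprogression`, `pr_sd` (both actual good) and
#' `true_pd` (actual poor).
#'
#' @param tab data.frame/matrix with a `predicted` column or rownames
#'   `good`/`poor` and the three subgroup columns.
#' @return `confusion_counts`.
#' @export
confusion_from_subgroups <- function(tab) {
  tab <- as.data.frame(tab)
  if ("predicted" %in% names(tab)) {
    rownames(tab) <- tab$predicted
    tab$predicted <- NULL
  }
  need <- c("pseudoprogression", "pr_sd", "true_pd")
  if (!all(need %in% names(tab)) || !all(c("good", "poor") %in% rownames(tab)))
    rader_abort("subgroup table needs good/poor rows and pseudoprogression/pr_sd/true_pd columns",
                "format")
  confusion_counts(
    tp = tab["good", "pseudoprogression"] + tab["good", "pr_sd"],
    fn = tab["poor", "pseudoprogression"] + tab["poor", "pr_sd"],
    fp = tab["good", "true_pd"],
    tn = tab["poor", "true_pd"],
    subgroups = list(
      predicted_good = unlist(tab["good", need]),
      predicted_poor = unlist(tab["poor", need])
    ))
}

#' Sensitivity, specificity, accuracy from confusion counts
#'
#' @param counts a [confusion_counts()].
#' @return list with `sen`, `spe`, `acc` (fractions) and
#'   `sen_str`/`spe_str`/`acc_str` (`"x/y"` forms).
#' @export
confusion_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  pos <- counts$tp + counts$fn
  neg <- counts$tn + counts$fp
  if (pos == 0 || neg == 0)
    rader_abort("metrics undefined with an empty class", "metric")
  total <- pos + neg
  list(sen = counts$tp / pos, spe = counts$tn / neg,
       acc = (counts$tp + counts$tn) / total,
       sen_str = sprintf("%d/%d", counts$tp, pos),
       spe_str = sprintf("%d/%d", counts$tn, neg),
       acc_str = sprintf("%d/%d", counts$tp + counts$tn, total))
}

format_pct <- function(x) sprintf("%.2f%%", round(x, 3) * 100)

#' ROC curve and rank-based AUC
#'
#' AUC is the Mann-Whitney statistic (ties counted half); the curve
#' holds one point per distinct threshold plus the (0,0) and (1,1)
#' endpoints, so the trapezoidal area under the emitted curve equals the
#' rank AUC exactly.
#'
#' @param scores per-sample good-class score.
#' @param labels good/poor per sample (both classes present).
#' @return list with `auc` and `curve` (data.frame `fpr`, `tpr`,
#'   `threshold`).
#' @export
roc_auc <- function(scores, labels) {
  good <- as.character(labels) == "good"
  if (all(good) || !any(good))
    rader_abort("ROC undefined with a single class", "metric")
  auc <- rank_auc(scores, good)
  th <- sort(unique(scores), decreasing = TRUE)
  pts <- t(vapply(th, function(s) {
    c(fpr = sum(scores >= s & !good) / sum(!good),
      tpr = sum(scores >= s & good) / sum(good))
  }, numeric(2)))
  curve <- data.frame(fpr = c(0, pts[, 1], 1), tpr = c(0, pts[, 2], 1),
                      threshold = c(Inf, th, -Inf))
  list(auc = auc, curve = curve)
}

# two-sided Mann-Whitney p for score separation (normal approximation
# with tie correction; sample sizes here are small but this mirrors the
# AUC-consistent rank test)
mann_whitney_p <- function(scores, labels) {
  good <- as.character(labels) == "good"
  n1 <- sum(good); n0 <- sum(!good)
  r <- rank(scores)
  U <- sum(r[good]) - n1 * (n1 + 1) / 2
  mu <- n1 * n0 / 2
  n <- n1 + n0
  ties <- table(scores)
  sig2 <- n1 * n0 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sig2 <= 0) return(1)
  z <- (abs(U - mu) - 0.5) / sqrt(sig2)
  2 * pnorm(-max(z, 0))
}

#' Compare the seven feature combinations end-to-end
#'
#' For each combination: assemble the requested provenance columns,
#' z-score on the training arm, screen and redundancy-filter, train the
#' Pareto model set, compute fusion weights, fuse validation
#' predictions, and tabulate SEN / SPE / ACC / AUC plus the
#' Mann-Whitney p of the score separation and the retained feature set.
#'
#' @param tables named list `pre`/`post`/`delta` of row-aligned
#'   feature matrices with an `arm` column, or a combined matrix (then
#'   split by prefix).
#' @param config an [automo_config()].
#' @param combos combinations to run (default all seven, in reporting
#'   order).
#' @param threshold redundancy-filter correlation cutoff.
#' @return object of class `evaluation_report`: `table` (one row per
#'   combination), `best` (max validation AUC), `details` (per-combo
#'   archives, selections, predictions).
#' @export
compare_combinations <- function(tables, config = automo_config(),
                                 combos = combination_names(),
                                 threshold = 0.8) {
  if (inherits(tables, "feature_matrix")) tables <- split_provenance(tables)
  details <- list()
  rows <- lapply(combos, function(combo) {
    res <- run_combination(tables, combo, config, threshold)
    details[[combo]] <<- res
    data.frame(combination = combo,
               n_features = length(res$selection$retained),
               sen = res$metrics$sen, spe = res$metrics$spe,
               acc = res$metrics$acc, auc = res$auc, p = res$p,
               stringsAsFactors = FALSE)
  })
  table <- do.call(rbind, rows)
  structure(list(table = table,
                 best = table$combination[which.max(table$auc)],
                 details = details),
            class = "evaluation_report")
}

# one combination: prep -> train -> weights -> fuse -> score validation
run_combination <- function(tables, combo, config, threshold = 0.8) {
  fm <- assemble_combination(tables, combo)
  if (is.null(fm$arm)) rader_abort("tables need an arm column", "cohort")
  train <- fm_subset(fm, rows = fm$arm == "train")
  val <- fm_subset(fm, rows = fm$arm == "validation")
  z <- fit_apply_zscore(train, val)
  screen <- t_screen(z$train)
  sel <- redundancy_filter(z$train, screen, threshold = threshold)
  keep <- match(sel$retained, colnames(z$train$x))
  tr <- fm_subset(z$train, cols = keep)
  va <- fm_subset(z$others[[1]], cols = keep)
  archive <- train_automo(tr, config)
  weights <- compute_weights(archive)
  pred <- predict_fused(archive, va, weights)
  cm <- confusion_counts(
    tp = sum(pred$label == "good" & va$label == "good"),
    fn = sum(pred$label == "poor" & va$label == "good"),
    fp = sum(pred$label == "good" & va$label == "poor"),
    tn = sum(pred$label == "poor" & va$label == "poor"))
  roc <- roc_auc(pred$p_good, va$label)
  list(combo = combo, selection = sel, archive = archive, weights = weights,
       predictions = pred, metrics = confusion_metrics(cm), auc = roc$auc,
       roc = roc$curve, p = mann_whitney_p(pred$p_good, va$label))
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Validation performance by feature combination\n")
  tab <- x$table
  tab$sen <- sprintf("%.3f", tab$sen); tab$spe <- sprintf("%.3f", tab$spe)
  tab$acc <- sprintf("%.3f", tab$acc); tab$auc <- sprintf("%.3f", tab$auc)
  tab$p <- ifelse(x$table$p < 1e-4, "<0.0001", sprintf("%.4f", x$table$p))
  print(tab, row.names = FALSE)
  cat("best combination (max AUC):", x$best, "\n")
  invisible(x)
}
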