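# Model weighting and evidential-reasoning (Dempster-Shafer style)
# fusion of the Pareto model set's probability outputs.

#' Compute fusion weights from archive objectives
#'
#' A model earns a raw weight only when its sensitivity/specificity
#' ratio shows balance: with `r = min(f_sen/f_spe, f_spe/f_sen)`, raw
#' `w = r + AUC` when `r >= 0.5` and 0 otherwise (both printed branches
#' coincide at ratio 1, so the symmetric form is exact). A zero
#' sensitivity or specificity makes the ratio undefined and the weight
#' 0. Raw weights are then normalized to sum 1 over all models. If every
#' raw weight is 0 the highest-AUC model gets weight 1, with a warning
#' (small archives would otherwise be brittle).
#'
#' @param archive a [train_automo()] result, or a list of candidates
#'   with `objectives`.
#' @return list of class `fusion_weights`: `omega` (normalized), `raw`,
#'   `zero_set` (indices with raw weight 0).
#' @export
compute_weights <- function(archive) {
  models <- if (inherits(archive, "pareto_archive")) archive$models
            else archive
  if (length(models) == 0) rader_abort("empty archive", "config")
  raw <- vapply(models, function(cand) {
    o <- cand$objectives
    sen <- o[["f_sen"]]; spe <- o[["f_spe"]]
    if (sen <= 0 || spe <= 0) return(0)
    r <- min(sen / spe, spe / sen)
    if (r >= 0.5) r + o[["auc"]] else 0
  }, numeric(1))
  if (all(raw == 0)) {
    warning("all fusion weights zero; falling back to the highest-AUC model",
            call. = FALSE)
    auc <- vapply(models, function(cand) cand$objectives[["auc"]], numeric(1))
    raw[which.max(auc)] <- 1
  }
  omega <- raw / sum(raw)
  structure(list(omega = omega, raw = raw, zero_set = which(raw == 0)),
            class = "fusion_weights")
}

#' Fuse model probability outputs by the evidential-reasoning rule
#'
#' Each model's two-class probability vector `(p_good, p_poor)` is
#' discounted by its weight into basic masses `omega_j * p_ij` with
#' residue `1 - omega_j` on the whole frame, and the discounted masses
#' are combined across models:
#' `P*_i  proportional to  prod_j(omega_j p_ij + 1 - omega_j) - prod_j(1 - omega_j)`,
#' normalized so `P*_good + P*_poor = 1` exactly. Zero-weight models
#' contribute a factor of 1 and drop out identically.
#'
#' @param outputs matrix (models x 2, columns good/poor) or list of
#'   length-2 probability vectors summing to 1.
#' @param weights a [compute_weights()] result (or numeric vector
#'   summing to 1).
#' @return list of class `fused_prediction`: `p_star` (named good/poor),
#'   `mu` (the ER normalization factor), `label`, `tie`.
#' @export
er_fuse <- function(outputs, weights) {
  omega <- if (inherits(weights, "fusion_weights")) weights$omega
           else as.numeric(weights)
  if (is.list(outputs)) outputs <- do.call(rbind, outputs)
  if (is.null(dim(outputs))) outputs <- matrix(outputs, ncol = 2)
  if (nrow(outputs) != length(omega))
    rader_abort("one weight per model output required", "config")
  if (any(outputs < -1e-9) ||
      any(abs(rowSums(outputs) - 1) > 1e-9))
    rader_abort("model outputs must be probabilities summing to 1", "config")
  if (all(omega == 0))
    rader_abort("fusion undefined with all-zero weights", "config")
  term <- vapply(1:2, function(i) prod(omega * outputs[, i] + 1 - omega),
                 numeric(1))
  K <- prod(1 - omega)
  mu <- 1 / (sum(term) - K)
  p <- (term - K) / (sum(term) - 2 * K)
  names(p) <- c("good", "poor")
  tie <- abs(p[1] - p[2]) < 1e-12
  structure(list(p_star = p, mu = mu,
                 label = decide_label_p(p), tie = unname(tie)),
            class = "fused_prediction")
}

decide_label_p <- function(p) {
  # exact tie resolves to "good" (flagged via `tie`)
  if (p[["poor"]] > p[["good"]]) "poor" else "good"
}

#' Final label of a fused prediction
#'
#' The class with maximal fused probability; an exact tie (difference
#' below 1e-12) resolves to `good` and is flagged.
#'
#' @param fused a [er_fuse()] result.
#' @return `"good"` or `"poor"`.
#' @export
decide_label <- function(fused) {
  stopifnot(inherits(fused, "fused_prediction"))
  fused$label
}

#' Fuse archive predictions for a cohort
#'
#' @param archive a [train_automo()] result.
#' @param fm feature matrix to predict.
#' @param weights optional precomputed [compute_weights()].
#' @return data.frame: `patient_id`, `p_good`, `p_poor`, `label`, `tie`.
#' @export
predict_fused <- function(archive, fm, weights = compute_weights(archive)) {
  probs <- predict_archive(archive, fm)  # n x J of P(good)
  rows <- lapply(seq_len(nrow(probs)), function(i) {
    fp <- er_fuse(cbind(probs[i, ], 1 - probs[i, ]), weights)
    data.frame(patient_id = fm$patient_id[i],
               p_good = fp$p_star[["good"]], p_poor = fp$p_star[["poor"]],
               label = fp$label, tie = fp$tie, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
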