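# Gray-level co-occurrence (Haralick) texture features.

#' GLCM extraction settings
#'
#' Defaults: 32 gray levels, distances 1, 2, 4 pixels, angles 0/45/90/135
#' degrees with angle averaging. Gray levels are quantized to
#' `n_gray_levels` equal-width bins over the ROI's own min-max range, so
#' texture features are invariant to positive rescaling of the image.
#'
#' @param n_gray_levels number of quantization bins (>= 2).
#' @param distances integer pixel offsets.
#' @param angles angles in degrees, subset of `{0, 45, 90, 135}`.
#' @return list of settings.
#' @export
glcm_settings <- function(n_gray_levels = 32L, distances = c(1L, 2L, 4L),
                          angles = c(0, 45, 90, 135)) {
  if (!is_count(n_gray_levels) || n_gray_levels < 2)
    rader_abort("n_gray_levels must be an integer >= 2", "config")
  if (!all(angles %in% c(0, 45, 90, 135)))
    rader_abort("angles must be a subset of {0, 45, 90, 135}", "config")
  if (any(distances < 1) || any(distances != floor(distances)))
    rader_abort("distances must be positive integers", "config")
  list(n_gray_levels = as.integer(n_gray_levels),
       distances = as.integer(distances), angles = angles)
}

glcm_stat_names <- c("energy", "entropy", "correlation", "contrast",
                     "texture_variance", "sum_mean", "inertia",
                     "cluster_shade", "cluster_prominence", "homogeneity",
                     "max_probability", "inverse_variance")

# offset (drow, dcol) for an angle/distance, image rows increasing downward
glcm_offset <- function(angle, d) {
  switch(as.character(angle),
    "0"   = c(0L, d),
    "45"  = c(-d, d),
    "90"  = c(-d, 0L),
    "135" = c(-d, -d))
}

# symmetric normalized co-occurrence matrix for one offset, or NULL when
# the offset admits no in-mask pixel pair
glcm_matrix <- function(q, mask, offset, L) {
  nr <- nrow(q); nc <- ncol(q)
  dr <- offset[1]; dc <- offset[2]
  r0 <- max(1L, 1L - dr):min(nr, nr - dr)
  c0 <- max(1L, 1L - dc):min(nc, nc - dc)
  if (length(r0) < 1 || length(c0) < 1) return(NULL)
  a <- q[r0, c0, drop = FALSE]
  b <- q[r0 + dr, c0 + dc, drop = FALSE]
  ok <- mask[r0, c0, drop = FALSE] & mask[r0 + dr, c0 + dc, drop = FALSE]
  if (!any(ok)) return(NULL)
  ai <- a[ok]; bi <- b[ok]
  counts <- matrix(tabulate(c((bi - 1L) * L + ai, (ai - 1L) * L + bi),
                            nbins = L * L), L, L)
  counts / sum(counts)
}

glcm_stats <- function(P, strict) {
  L <- nrow(P)
  lev <- seq_len(L)
  I <- matrix(lev, L, L)
  J <- t(I)
  px <- rowSums(P)
  mu <- sum(lev * px)
  sig2 <- sum((lev - mu)^2 * px)
  pos <- P > 0
  entropy <- -sum(P[pos] * log2(P[pos]))
  contrast <- sum((I - J)^2 * P)
  offd <- I != J
  out <- c(
    energy = sum(P^2),
    entropy = entropy,
    correlation = NA_real_,
    contrast = contrast,
    texture_variance = sum((I - mu)^2 * P),
    sum_mean = sum((I + J) * P),
    inertia = contrast,
    cluster_shade = sum((I + J - 2 * mu)^3 * P),
    cluster_prominence = sum((I + J - 2 * mu)^4 * P),
    homogeneity = sum(P / (1 + abs(I - J))),
    max_probability = max(P),
    inverse_variance = sum(P[offd] / (I[offd] - J[offd])^2)
  )
  if (sig2 > 0) {
    out["correlation"] <- (sum(I * J * P) - mu^2) / sig2
  } else if (strict) {
    rader_abort("degenerate ROI: GLCM correlation undefined (zero variance)",
                "degenerate_roi")
  }
  out
}

#' GLCM texture features of a ROI
#'
#' Quantizes the masked pixels to `n_gray_levels` equal-width bins over
#' the ROI min-max, builds one symmetric normalized co-occurrence matrix
#' per (distance, angle) from pixel pairs that both lie inside the mask,
#' computes the 12 Haralick-style statistics per matrix, and averages
#' them over angles within each distance. Feature names encode the
#' distance (`energy_d1`, ...). Entropy uses log base 2; homogeneity is
#' `sum p/(1+|i-j|)`; inverse variance sums `p/(i-j)^2` off the
#' diagonal; contrast and inertia share the standard formula and are
#' both emitted (the redundancy filter removes one downstream).
#'
#' A ROI that is constant after quantization takes the degenerate path:
#' energy 1, entropy 0, max_probability 1, and a degenerate-ROI error
#' for correlation under `strict = TRUE` (omitted when `strict = FALSE`).
#' An offset with no valid pixel pair is skipped; if every angle at some
#' distance is empty the ROI is degenerate for that catalogue and an
#' error is raised.
#'
#' @param scan a [roi_scan()].
#' @param settings see [glcm_settings()].
#' @param strict raise on undefined statistics (default `TRUE`).
#' @return named numeric vector, `12 * length(distances)` entries (minus
#'   omitted ones when `strict = FALSE`).
#' @export
glcm_texture_features <- function(scan, settings = glcm_settings(),
                                  strict = TRUE) {
  v <- masked_values(scan)
  L <- settings$n_gray_levels
  lo <- min(v); hi <- max(v)
  q <- matrix(1L, nrow(scan$image), ncol(scan$image))
  if (hi > lo) {
    qv <- pmin(floor((scan$image - lo) / (hi - lo) * L), L - 1) + 1
    qv[scan$image < lo] <- 1          # mask-exterior values are irrelevant
    qv[scan$image > hi] <- L
    q <- matrix(as.integer(qv), nrow(scan$image), ncol(scan$image))
  }
  out <- numeric(0)
  for (d in settings$distances) {
    mats <- list()
    for (ang in settings$angles) {
      P <- glcm_matrix(q, scan$mask, glcm_offset(ang, d), L)
      if (!is.null(P)) mats[[length(mats) + 1L]] <- P
    }
    if (length(mats) == 0L)
      rader_abort(sprintf(
        "degenerate ROI: no valid pixel pair at any angle for distance %d", d),
        "degenerate_roi")
    stats <- lapply(mats, glcm_stats, strict = strict)
    avg <- Reduce(`+`, stats) / length(stats)
    if (!strict && anyNA(avg)) avg <- avg[!is.na(avg)]
    names(avg) <- paste0(names(avg), "_d", d)
    out <- c(out, avg)
  }
  out
}
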