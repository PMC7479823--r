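# Synthetic cohort: elliptical lesion phantoms whose size and texture
# evolve differently by response subgroup, including a pseudoprogression
# subtype that grows like a progressor but whose intensity/texture
# evolution follows the responder distribution.

#' Specification of a synthetic cohort
#'
#' Defaults mirror the melanoma immunotherapy study design this package
#' emulates: 34 training patients (18 true progression / 2
#' pseudoprogression / 14 SD-PR) and 16 validation patients (9 / 3 / 4).
#' `effect_size` is the dimensionless separation between the class
#' feature distributions (0 = null cohort); `noise_sd` the lesion
#' texture heterogeneity scale in gray-level units.
#'
#' @param n_train,n_val arm sizes.
#' @param train_counts,val_counts named counts `(true_pd,
#'   pseudoprogression, sd_pr)` summing to the arm size.
#' @param effect_size class separation, >= 0 (default 2).
#' @param noise_sd texture heterogeneity scale, > 0 (default 10).
#' @param image_side image side in pixels, >= 16 (default 64).
#' @param seed integer seed; generation is fully deterministic given it.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_train = 34L, n_val = 16L,
                        train_counts = c(true_pd = 18L, pseudoprogression = 2L,
                                         sd_pr = 14L),
                        val_counts = c(true_pd = 9L, pseudoprogression = 3L,
                                       sd_pr = 4L),
                        effect_size = 2, noise_sd = 10, image_side = 64L,
                        seed = 1L) {
  check_counts <- function(counts, n, arm) {
    if (!setequal(names(counts), c("true_pd", "pseudoprogression", "sd_pr")))
      rader_abort(paste0(arm, " counts need names true_pd/pseudoprogression/sd_pr"),
                  "cohort_spec")
    if (any(counts < 0) || sum(counts) != n)
      rader_abort(sprintf("%s subgroup counts (%s) do not sum to arm size %d",
                          arm, paste(counts, collapse = "+"), n),
                  "cohort_spec")
  }
  if (!is_count(n_train) || !is_count(n_val))
    rader_abort("arm sizes must be non-negative integers", "cohort_spec")
  check_counts(train_counts, n_train, "train")
  check_counts(val_counts, n_val, "validation")
  if (!is_number(effect_size) || effect_size < 0)
    rader_abort("effect_size must be >= 0", "cohort_spec")
  if (!is_number(noise_sd) || noise_sd <= 0)
    rader_abort("noise_sd must be > 0", "cohort_spec")
  if (!is_count(image_side) || image_side < 16)
    rader_abort("image_side must be an integer >= 16", "cohort_spec")
  structure(list(n_train = as.integer(n_train), n_val = as.integer(n_val),
                 train_counts = train_counts[c("true_pd", "pseudoprogression",
                                               "sd_pr")],
                 val_counts = val_counts[c("true_pd", "pseudoprogression",
                                           "sd_pr")],
                 effect_size = effect_size, noise_sd = noise_sd,
                 image_side = as.integer(image_side),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

subgroup_label <- function(subgroup) {
  ifelse(subgroup == "true_pd", "poor", "good")
}

cohort_plan <- function(spec) {
  arm <- rep(c("train", "validation"), c(spec$n_train, spec$n_val))
  subgroup <- c(rep(names(spec$train_counts), spec$train_counts),
                rep(names(spec$val_counts), spec$val_counts))
  data.frame(arm = arm, subgroup = subgroup, stringsAsFactors = FALSE)
}

# separable Gaussian blur with replicated edges
gaussian_blur <- function(m, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  pad_conv <- function(v) {
    vp <- c(rep(v[1], r), v, rep(v[length(v)], r))
    as.numeric(stats::filter(vp, k, sides = 2))[(r + 1):(r + length(v))]
  }
  m1 <- apply(m, 2, pad_conv)
  t(apply(t(m1), 2, pad_conv))
}

ellipse_mask <- function(side, cy, cx, a, b, phi) {
  rows <- matrix(seq_len(side) - 1, side, side)
  cols <- t(rows)
  dx <- cols - cx; dy <- rows - cy
  u <- dx * cos(phi) + dy * sin(phi)
  w <- -dx * sin(phi) + dy * cos(phi)
  (u / a)^2 + (w / b)^2 <= 1
}

render_lesion <- function(side, cy, cx, a, b, phi, level, heterogeneity) {
  mask <- ellipse_mask(side, cy, cx, a, b, phi)
  field <- 0.7 * gaussian_blur(matrix(rnorm(side * side), side, side), 1.5) +
    0.3 * matrix(rnorm(side * side), side, side)
  field <- field / sd(field)
  img <- 20 + 3 * matrix(rnorm(side * side), side, side)  # background
  img[mask] <- level + heterogeneity * field[mask]
  list(image = img, mask = mask)
}

# Subgroup-specific evolution draws. Pseudoprogression shares the
# responder-like appearance sampler exactly (only its geometry differs),
# so its delta intensity/texture statistics are distributed as sd_pr's.
draw_evolution <- function(subgroup, e, noise_sd) {
  growth <- switch(subgroup,
    true_pd = ,
    pseudoprogression = 1 + e * (0.1 + 0.1 * runif(1)),
    sd_pr = 1 - e * (0.05 + 0.075 * runif(1)))
  appearance <- if (subgroup == "true_pd") {
    list(h_mult = exp(0.15 * e + 0.08 * rnorm(1)),
         level_shift = e * 0.4 * noise_sd + 0.1 * noise_sd * rnorm(1))
  } else {
    list(h_mult = exp(-0.15 * e + 0.08 * rnorm(1)),
         level_shift = -e * 0.4 * noise_sd + 0.1 * noise_sd * rnorm(1))
  }
  c(list(growth = growth), appearance)
}

generate_patient <- function(id, arm, subgroup, spec) {
  side <- spec$image_side
  e <- spec$effect_size
  cxy <- (side - 1) / 2 + runif(2, -2, 2)
  a <- runif(1, side / 10, side / 6)          # major semi-axis (px)
  ratio <- runif(1, 1, 2.5)
  b <- a / ratio
  phi <- runif(1, 0, pi)
  level <- rnorm(1, 100, 5)
  h_pre <- spec$noise_sd * exp(rnorm(1, 0, 0.15))
  ev <- draw_evolution(subgroup, e, spec$noise_sd)
  s <- sqrt(ev$growth)
  # small per-axis jitter: the post lesion is re-delineated, so its
  # shape never matches the scaled baseline exactly (all subgroups)
  jit <- exp(rnorm(2, 0, 0.02))
  pre <- render_lesion(side, cxy[1], cxy[2], a, b, phi, level, h_pre)
  post <- render_lesion(side, cxy[1], cxy[2], a * s * jit[1], b * s * jit[2],
                        phi, level + ev$level_shift, h_pre * ev$h_mult)
  list(patient_id = id, arm = arm, subgroup = subgroup,
       label = subgroup_label(subgroup),
       pre_scan = roi_scan(pre$image, pre$mask, examination = "pre"),
       post_scan = roi_scan(post$image, post$mask, examination = "post"))
}

#' Generate a synthetic image cohort
#'
#' Deterministic for a fixed `spec$seed`. Each patient gets a pre and a
#' post elliptical lesion with textured interior; at the default effect
#' size the progressing subgroups (`true_pd`, `pseudoprogression`) grow
#' by >= 20% in area while `sd_pr` lesions shrink, and texture
#' heterogeneity / mean attenuation evolve in opposite directions for
#' progressors vs everyone else. Pseudoprogression lesions grow like
#' progressors but their appearance evolution is drawn from the same
#' distribution as `sd_pr`. All contrasts scale linearly with
#' `effect_size`; at 0 every subgroup draws from identical distributions
#' (null cohort).
#'
#' @param spec a [cohort_spec()].
#' @return list of patients (`patient_id`, `arm`, `subgroup`, `label`,
#'   `pre_scan`, `post_scan`).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  plan <- cohort_plan(spec)
  with_seed(spec$seed, {
    lapply(seq_len(nrow(plan)), function(i) {
      generate_patient(sprintf("P%03d", i), plan$arm[i], plan$subgroup[i], spec)
    })
  })
}

#' Tabulate a cohort's arms, subgroups and labels
#'
#' @param patients list from [generate_cohort()].
#' @return list with `n`, per-arm subgroup count table, label counts,
#'   and `pseudoprogression_fraction`.
#' @export
cohort_summary <- function(patients) {
  arm <- vapply(patients, `[[`, "", "arm")
  subgroup <- vapply(patients, `[[`, "", "subgroup")
  label <- vapply(patients, `[[`, "", "label")
  list(n = length(patients),
       subgroups = table(arm, subgroup),
       labels = table(label),
       pseudoprogression_fraction = mean(subgroup == "pseudoprogression"))
}

#' Write a cohort to disk (NRRD images + manifest CSV)
#'
#' @param patients list from [generate_cohort()].
#' @param dir output directory (created).
#' @param encoding NRRD encoding (`"ascii"` or `"raw"`).
#' @return path of the manifest CSV.
#' @export
write_cohort <- function(patients, dir, encoding = "ascii") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(patients, function(p) {
    paths <- file.path(dir, paste0(p$patient_id, "_",
                                   c("pre", "pre_mask", "post", "post_mask"),
                                   ".nrrd"))
    write_nrrd(p$pre_scan$image, paths[1], p$pre_scan$spacing, encoding)
    write_nrrd(p$pre_scan$mask + 0, paths[2], p$pre_scan$spacing, encoding)
    write_nrrd(p$post_scan$image, paths[3], p$post_scan$spacing, encoding)
    write_nrrd(p$post_scan$mask + 0, paths[4], p$post_scan$spacing, encoding)
    data.frame(patient_id = p$patient_id, arm = p$arm, subgroup = p$subgroup,
               label = p$label, pre_image = paths[1], pre_mask = paths[2],
               post_image = paths[3], post_mask = paths[4])
  })
  manifest <- file.path(dir, "manifest.csv")
  write.csv(do.call(rbind, rows), manifest, row.names = FALSE)
  manifest
}

#' Read a cohort from a manifest CSV
#'
#' @param manifest_path manifest as written by [write_cohort()].
#' @return list of patients.
#' @export
read_cohort <- function(manifest_path) {
  df <- read.csv(manifest_path, stringsAsFactors = FALSE)
  need <- c("patient_id", "arm", "subgroup", "label", "pre_image", "pre_mask",
            "post_image", "post_mask")
  if (!all(need %in% names(df)))
    rader_abort("manifest missing required columns", "format")
  lapply(seq_len(nrow(df)), function(i) {
    list(patient_id = df$patient_id[i], arm = df$arm[i],
         subgroup = df$subgroup[i], label = df$label[i],
         pre_scan = read_roi_scan(df$pre_image[i], df$pre_mask[i], "pre"),
         post_scan = read_roi_scan(df$post_image[i], df$post_mask[i], "post"))
  })
}

# columns that carry the class signal in the direct feature-table sampler
informative_features <- function() {
  c("maximum", "mean", "stand_deviation", "skewness", "entropy_d1",
    "correlation_d1", "cluster_shade_d2", "volume", "minor_diameter")
}

#' Sample a feature table directly from class-conditional Gaussians
#'
#' Fast alternative to image generation for testing downstream stages:
#' every column of the extractor's catalogue is drawn N(0, 1), except a
#' designated informative subset within the provenance groups named in
#' `signal_in`, where good-response rows get mean `+effect_size/2` and
#' poor-response rows `-effect_size/2`. Column names match the
#' extractor's output exactly, so downstream stages cannot distinguish
#' the source.
#'
#' @param spec a [cohort_spec()].
#' @param signal_in provenance groups carrying signal (default all
#'   three).
#' @param settings GLCM settings fixing the catalogue.
#' @return a [feature_matrix()] with an `arm` column covering both arms.
#' @export
generate_feature_table <- function(spec, signal_in = c("pre", "post", "delta"),
                                   settings = glcm_settings()) {
  stopifnot(inherits(spec, "cohort_spec"))
  signal_in <- match.arg(signal_in, several.ok = TRUE)
  catalogue <- feature_catalogue(settings)
  cols <- as.vector(vapply(c("pre", "post", "delta"),
                           function(p) paste0(p, "_", catalogue),
                           character(length(catalogue))))
  plan <- cohort_plan(spec)
  label <- subgroup_label(plan$subgroup)
  shift_cols <- as.vector(vapply(signal_in,
                                 function(p) paste0(p, "_", informative_features()),
                                 character(length(informative_features()))))
  with_seed(spec$seed, {
    x <- matrix(rnorm(nrow(plan) * length(cols)), nrow(plan), length(cols),
                dimnames = list(NULL, cols))
    shift <- ifelse(label == "good", spec$effect_size / 2,
                    -spec$effect_size / 2)
    x[, shift_cols] <- x[, shift_cols] + shift
    feature_matrix(x, label, arm = plan$arm,
                   patient_id = sprintf("P%03d", seq_len(nrow(plan))))
  })
}

#' Split a combined feature table into provenance tables
#'
#' @param fm feature matrix with `pre_`/`post_`/`delta_`-prefixed
#'   columns.
#' @return named list `pre`, `post`, `delta` of feature matrices.
#' @export
split_provenance <- function(fm) {
  out <- lapply(c(pre = "pre", post = "post", delta = "delta"), function(p) {
    cols <- which(startsWith(colnames(fm$x), paste0(p, "_")))
    fm_subset(fm, cols = cols)
  })
  out
}
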