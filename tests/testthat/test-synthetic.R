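# Synthetic cohort generator: bookkeeping, determinism, class structure.

test_that("default cohort reproduces the study's arm and label bookkeeping", {
  spec <- cohort_spec(seed = 7)
  patients <- generate_cohort(spec)
  s <- cohort_summary(patients)
  expect_equal(s$n, 50)
  expect_equal(unname(s$labels["good"]), 23)   # 2 + 14 + 3 + 4
  expect_equal(unname(s$labels["poor"]), 27)   # 18 + 9
  expect_equal(s$pseudoprogression_fraction, 0.1)
  expect_equal(unname(s$subgroups["train", "true_pd"]), 18)
  expect_equal(unname(s$subgroups["validation", "pseudoprogression"]), 3)
})

test_that("label/subgroup invariant holds for every patient", {
  patients <- generate_cohort(tiny_spec(seed = 3))
  for (p in patients)
    expect_identical(p$label, if (p$subgroup == "true_pd") "poor" else "good")
})

test_that("cohort generation is deterministic under a fixed seed", {
  a <- generate_cohort(tiny_spec(seed = 5))
  b <- generate_cohort(tiny_spec(seed = 5))
  expect_identical(a, b)
  c2 <- generate_cohort(tiny_spec(seed = 6))
  expect_false(identical(a[[1]]$pre_scan$image, c2[[1]]$pre_scan$image))
})

test_that("subgroup geometry evolves as designed at the default effect size", {
  patients <- generate_cohort(cohort_spec(seed = 11))
  area <- function(s) sum(s$mask)
  for (p in patients) {
    growth <- area(p$post_scan) / area(p$pre_scan)
    if (p$subgroup %in% c("true_pd", "pseudoprogression")) {
      expect_gte(growth, 1.15)  # >= 20% modulo pixelation + re-delineation
    } else {
      expect_lte(growth, 1.02)
    }
  }
})

test_that("inconsistent subgroup counts are rejected", {
  expect_error(cohort_spec(n_train = 10,
                           train_counts = c(true_pd = 5, pseudoprogression = 1,
                                            sd_pr = 5)),
               class = "rader_error_cohort_spec")
  expect_error(cohort_spec(effect_size = -1),
               class = "rader_error_cohort_spec")
  expect_error(cohort_spec(image_side = 8), class = "rader_error_cohort_spec")
  # counts (2,1,1) on an arm of 4 are fine
  s <- cohort_spec(n_train = 4,
                   train_counts = c(true_pd = 2, pseudoprogression = 1,
                                    sd_pr = 1),
                   n_val = 4,
                   val_counts = c(true_pd = 2, pseudoprogression = 1,
                                  sd_pr = 1))
  expect_s3_class(s, "cohort_spec")
})

test_that("pseudoprogression grows in size but its appearance deltas follow sd_pr", {
  # large cohort so the two-sample test has power to detect any difference
  spec <- cohort_spec(n_train = 150,
                      train_counts = c(true_pd = 50, pseudoprogression = 50,
                                       sd_pr = 50),
                      n_val = 0,
                      val_counts = c(true_pd = 0, pseudoprogression = 0,
                                     sd_pr = 0),
                      seed = 21)
  patients <- generate_cohort(spec)
  sub <- vapply(patients, `[[`, "", "subgroup")
  d_mean <- vapply(patients, function(p) {
    mean(masked_values(p$post_scan)) - mean(masked_values(p$pre_scan))
  }, numeric(1))
  d_sd <- vapply(patients, function(p) {
    sd(masked_values(p$post_scan)) - sd(masked_values(p$pre_scan))
  }, numeric(1))
  d_area <- vapply(patients, function(p) {
    sum(p$post_scan$mask) - sum(p$pre_scan$mask)
  }, numeric(1))
  expect_true(all(d_area[sub == "pseudoprogression"] > 0))
  # pseudoprogression vs sd_pr: appearance deltas indistinguishable
  expect_gt(t.test(d_mean[sub == "pseudoprogression"],
                   d_mean[sub == "sd_pr"])$p.value, 0.01)
  expect_gt(t.test(d_sd[sub == "pseudoprogression"],
                   d_sd[sub == "sd_pr"])$p.value, 0.01)
  # ...but clearly different from true_pd
  expect_lt(t.test(d_mean[sub == "pseudoprogression"],
                   d_mean[sub == "true_pd"])$p.value, 1e-6)
})

test_that("effect_size 0 yields a null cohort", {
  patients <- generate_cohort(cohort_spec(effect_size = 0, seed = 31,
                                          image_side = 48))
  lab <- vapply(patients, `[[`, "", "label")
  d_mean <- vapply(patients, function(p) {
    mean(masked_values(p$post_scan)) - mean(masked_values(p$pre_scan))
  }, numeric(1))
  d_area <- vapply(patients, function(p) {
    sum(p$post_scan$mask) / sum(p$pre_scan$mask)
  }, numeric(1))
  expect_gt(t.test(d_mean[lab == "good"], d_mean[lab == "poor"])$p.value, 0.01)
  expect_gt(t.test(d_area[lab == "good"], d_area[lab == "poor"])$p.value, 0.01)
})

test_that("feature-table sampler matches the extractor catalogue and effect", {
  spec <- cohort_spec(n_train = 50,
                      train_counts = c(true_pd = 25, pseudoprogression = 5,
                                       sd_pr = 20),
                      n_val = 50,
                      val_counts = c(true_pd = 25, pseudoprogression = 5,
                                     sd_pr = 20),
                      effect_size = 2, seed = 13)
  fm <- generate_feature_table(spec)
  expect_equal(ncol(fm$x), 3 * length(feature_catalogue()))
  expect_identical(colnames(split_provenance(fm)$delta$x),
                   paste0("delta_", feature_catalogue()))
  # informative column separates classes strongly at d = 2, n = 50/class
  p_inf <- t.test(fm$x[fm$label == "good", "pre_mean"],
                  fm$x[fm$label == "poor", "pre_mean"])$p.value
  expect_lt(p_inf, 0.01)
  # null table: about 5% of columns reach p < 0.05
  null_fm <- generate_feature_table(cohort_spec(effect_size = 0, seed = 14))
  ps <- t_screen(null_fm)$p
  expect_lt(mean(ps < 0.05), 0.15)
})

test_that("cohort round-trips through NRRD + manifest", {
  patients <- generate_cohort(tiny_spec(seed = 9, side = 32))
  dir <- tempfile("cohort_")
  manifest <- write_cohort(patients, dir)
  back <- read_cohort(manifest)
  expect_equal(length(back), length(patients))
  expect_equal(back[[1]]$pre_scan$image, patients[[1]]$pre_scan$image,
               tolerance = 1e-12)
  expect_identical(back[[1]]$pre_scan$mask, patients[[1]]$pre_scan$mask)
  expect_identical(vapply(back, `[[`, "", "label"),
                   vapply(patients, `[[`, "", "label"))
})
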