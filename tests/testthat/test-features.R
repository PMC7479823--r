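# Intensity, GLCM texture, geometry, delta, and combination assembly.

test_that("intensity features match hand arithmetic and the moment oracle", {
  sc <- roi_scan(matrix(c(2, 4, 6, 99), 2, 2),
                 matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2))
  f <- intensity_features(sc)
  expect_equal(unname(f[c("mean", "sum", "median")]), c(4, 12, 4))
  expect_equal(unname(f["variance"]), 8 / 3)
  expect_equal(unname(f["stand_deviation"]), sqrt(8 / 3))

  v <- c(1, 2, 3, 4, 100)
  sc2 <- roi_scan(matrix(c(v, 0), 2, 3), matrix(c(rep(TRUE, 5), FALSE), 2, 3))
  f2 <- intensity_features(sc2)
  mo <- moment_oracle(v)
  expect_equal(unname(f2["skewness"]), mo$skewness)
  expect_equal(unname(f2["kurtosis"]), mo$kurtosis)
})

test_that("zero-variance ROIs raise degenerate errors for moment features", {
  sc <- roi_scan(matrix(5, 4, 4), matrix(TRUE, 4, 4))
  expect_error(intensity_features(sc), class = "rader_error_degenerate_roi")
  relaxed <- intensity_features(sc, strict = FALSE)
  expect_false(any(c("skewness", "kurtosis") %in% names(relaxed)))
  expect_equal(unname(relaxed["variance"]), 0)
  # single pixel
  one <- roi_scan(matrix(1:4, 2, 2),
                  matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2))
  expect_error(intensity_features(one), class = "rader_error_degenerate_roi")
})

test_that("constant ROI takes the degenerate GLCM path", {
  sc <- roi_scan(matrix(5, 6, 6), matrix(TRUE, 6, 6))
  expect_error(glcm_texture_features(sc, glcm_settings(distances = 1)),
               class = "rader_error_degenerate_roi")
  f <- glcm_texture_features(sc, glcm_settings(distances = 1), strict = FALSE)
  expect_equal(unname(f["energy_d1"]), 1)
  expect_equal(unname(f["entropy_d1"]), 0)
  expect_equal(unname(f["max_probability_d1"]), 1)
  expect_equal(unname(f["homogeneity_d1"]), 1)
  expect_false("correlation_d1" %in% names(f))
})

test_that("2x2 checkerboard matches the hand-built co-occurrence matrix", {
  img <- matrix(c(0, 1, 1, 0), 2, 2)
  sc <- roi_scan(img, matrix(TRUE, 2, 2))
  f <- glcm_texture_features(sc, glcm_settings(n_gray_levels = 2,
                                               distances = 1, angles = 0))
  # P = [[0, .5], [.5, 0]]
  expect_equal(unname(f["energy_d1"]), 0.5)
  expect_equal(unname(f["entropy_d1"]), 1)          # 1 bit
  expect_equal(unname(f["contrast_d1"]), 1)
  expect_equal(unname(f["max_probability_d1"]), 0.5)
  expect_equal(unname(f["correlation_d1"]), -1)     # perfectly anti-correlated
  expect_equal(unname(f["sum_mean_d1"]), 3)         # levels 1,2 always paired
})

test_that("contrast equals inertia for random ROIs", {
  for (seed in 1:5) {
    sc <- random_scan(seed = seed)
    f <- glcm_texture_features(sc)
    for (d in c(1, 2, 4))
      expect_identical(unname(f[paste0("contrast_d", d)]),
                       unname(f[paste0("inertia_d", d)]))
  }
})

test_that("geometry features recover closed forms for circle and rectangle", {
  circ <- circle_scan(radius = 10)
  g <- geometry_features(circ)
  expect_equal(unname(g["volume"]), pi * 100, tolerance = 0.02)
  expect_lt(unname(g["eccentricity"]), 0.1)
  expect_equal(unname(g["elongation"]), 1, tolerance = 0.01)

  rect <- rect_scan(w = 4, h = 2)
  gr <- geometry_features(rect)
  expect_equal(unname(gr["volume"]), 8)
  expect_equal(unname(gr["bounding_box_volume"]), 8)
  expect_equal(unname(gr["elongation"]), 0.5)  # h/w via continuous moments
  expect_equal(unname(gr["eccentricity"]), sqrt(1 - 0.25))
  expect_equal(unname(gr["perimeter"]), 12)    # crack length exact here
  expect_equal(unname(gr["orientation"]), 0)
})

test_that("minor <= major and eccentricity in [0,1) for random masks", {
  for (seed in 1:8) {
    g <- geometry_features(random_scan(seed = seed))
    expect_lte(g[["minor_diameter"]], g[["major_diameter"]])
    expect_gte(g[["eccentricity"]], 0)
    expect_lt(g[["eccentricity"]], 1)
  }
})

test_that("features are invariant to translation and 90-degree rotation", {
  sc <- random_scan(side = 30, seed = 9)
  full <- extract_features(sc)
  # translate by (3, 5) inside a larger canvas
  big_i <- matrix(0, 40, 40); big_m <- matrix(FALSE, 40, 40)
  big_i[4:33, 6:35] <- sc$image; big_m[4:33, 6:35] <- sc$mask
  shifted <- extract_features(roi_scan(big_i, big_m))
  skip_names <- c("orientation")
  keep <- setdiff(names(full), skip_names)
  expect_equal(shifted[keep], full[keep], tolerance = 1e-9)

  rot <- roi_scan(t(sc$image)[ncol(sc$image):1, ],
                  t(sc$mask)[ncol(sc$mask):1, ])
  rotated <- extract_features(rot)
  expect_equal(rotated[keep], full[keep], tolerance = 1e-9)
})

test_that("intensity and texture ignore mask-exterior pixels", {
  sc <- random_scan(seed = 11)
  img2 <- sc$image
  img2[!sc$mask] <- -1e6
  sc2 <- roi_scan(img2, sc$mask)
  expect_equal(extract_features(sc2), extract_features(sc), tolerance = 1e-12)
})

test_that("positive gray-level scaling acts as expected per feature class", {
  sc <- random_scan(seed = 13)
  f1 <- extract_features(sc)
  f2 <- extract_features(roi_scan(sc$image * 3.5, sc$mask))
  linear <- c("minimum", "maximum", "mean", "stand_deviation", "sum", "median")
  expect_equal(f2[linear], 3.5 * f1[linear], tolerance = 1e-9)
  invariant <- c("skewness", "kurtosis",
                 grep("_d[124]$", names(f1), value = TRUE))
  expect_equal(f2[invariant], f1[invariant], tolerance = 1e-9)
})

test_that("extraction is deterministic", {
  sc <- random_scan(seed = 17)
  expect_identical(extract_features(sc), extract_features(sc))
})

test_that("delta features subtract pre from post and guard provenance", {
  pre <- extract_features(random_scan(seed = 1))
  post <- extract_features(random_scan(seed = 2, examination = "post"))
  d <- delta_features(pre, post)
  expect_equal(as.numeric(d), as.numeric(post[names(pre)] - pre))
  expect_equal(as.numeric(delta_features(pre, pre)), rep(0, length(pre)))
  expect_error(delta_features(d, post), class = "rader_error_catalogue")
  expect_error(delta_features(pre[-1], post), class = "rader_error_catalogue")
})

test_that("the seven combinations assemble in order with prefixed columns", {
  fm <- gaussian_fm(n_per_class = 4, p = 6)
  n <- 2
  mk <- function(p) {
    x <- fm$x[, 1:n, drop = FALSE]
    colnames(x) <- paste0(p, "_", c("a", "b"))
    feature_matrix(x, fm$label)
  }
  tables <- list(pre = mk("pre"), post = mk("post"), delta = mk("delta"))
  expect_identical(combination_names(),
                   c("pre", "pre+delta", "post", "post+delta", "pre+post",
                     "pre+post+delta", "delta"))
  expect_equal(ncol(assemble_combination(tables, "pre")$x), n)
  expect_equal(ncol(assemble_combination(tables, "pre+post+delta")$x), 3 * n)
  got <- colnames(assemble_combination(tables, "pre+delta")$x)
  expect_identical(got, c("pre_a", "pre_b", "delta_a", "delta_b"))
  # row misalignment
  bad <- tables
  bad$post$patient_id <- rev(bad$post$patient_id)
  expect_error(assemble_combination(bad, "pre+post"),
               class = "rader_error_cohort")
  expect_error(assemble_combination(tables, "post+pre"),
               class = "rader_error_config")
})
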