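# The multi-objective immune search machinery.

test_that("stratified folds are deterministic and keep classes in training parts", {
  lab <- rep(c("good", "poor"), c(16, 18))
  f1 <- make_cv_folds(lab, 5, fold_seed = 3)
  f2 <- make_cv_folds(lab, 5, fold_seed = 3)
  expect_identical(f1, f2)
  expect_setequal(unique(f1), 1:5)
  for (k in 1:5)
    expect_length(unique(lab[f1 != k]), 2)
  # a class with a single member cannot be stratified
  expect_error(make_cv_folds(c("good", rep("poor", 9)), 5, 1),
               class = "rader_error_stratification")
})

test_that("candidate evaluation is deterministic and hits the separable limit", {
  fm <- gaussian_fm(n_per_class = 15, p = 4, d = 8, seed = 2)
  folds <- make_cv_folds(fm$label, 5, 7)
  cand <- radER:::new_candidate(10, 0.05, rep(TRUE, 4))
  e1 <- evaluate_candidate(cand, fm, folds)
  e2 <- evaluate_candidate(cand, fm, folds)
  expect_identical(e1$objectives, e2$objectives)
  expect_equal(unname(e1$objectives), c(1, 1, 1))
})

test_that("evaluation equals a hand-rolled CV of the plain SVM", {
  fm <- gaussian_fm(n_per_class = 12, p = 5, d = 1, seed = 3)
  folds <- make_cv_folds(fm$label, 5, 11)
  cand <- radER:::new_candidate(4, 0.25, rep(TRUE, 5))
  got <- evaluate_candidate(cand, fm, folds)$objectives
  # oracle: independent plain 5-fold CV loop over the same folds
  prob <- numeric(nrow(fm$x))
  for (k in 1:5) {
    m <- svm_train(fm$x[folds != k, ], fm$label[folds != k], 4, 0.25)
    prob[folds == k] <- svm_prob(m, fm$x[folds == k, , drop = FALSE])
  }
  good <- fm$label == "good"
  expect_equal(unname(got["f_sen"]), mean(prob[good] >= 0.5))
  expect_equal(unname(got["f_spe"]), mean(prob[!good] < 0.5))
  expect_equal(unname(got["auc"]), auc_oracle(prob, good))
})

test_that("permuted labels yield chance-level CV AUC", {
  with_seed(17, {
    x <- matrix(rnorm(200 * 4), 200, 4, dimnames = list(NULL, paste0("f", 1:4)))
    lab <- sample(rep(c("good", "poor"), 100))
  })
  fm <- feature_matrix(x, lab)
  folds <- make_cv_folds(fm$label, 5, 23)
  obj <- evaluate_candidate(radER:::new_candidate(1, 0.25, rep(TRUE, 4)),
                            fm, folds)$objectives
  expect_gt(obj[["auc"]], 0.35)
  expect_lt(obj[["auc"]], 0.65)
})

test_that("hybrid initialization is valid, seeded from top ranks, deterministic", {
  fm <- gaussian_fm(n_per_class = 20, p = 30, d = 1.5, seed = 4,
                    informative = 1:3)
  screen <- t_screen(fm)
  cfg <- automo_config()
  pop <- initialize_population(20, screen, cfg, seed = 5)
  expect_length(pop, 20)
  top <- order(screen$p)[1:20]
  for (i in seq_along(pop)) {
    expect_true(any(pop[[i]]$beta))
    expect_true(pop[[i]]$cost >= cfg$cost_range[1] &&
                  pop[[i]]$cost <= cfg$cost_range[2])
    if (i <= 10)  # seeded half draws only from the top-ranked pool
      expect_true(all(which(pop[[i]]$beta) %in% top))
  }
  expect_identical(pop, initialize_population(20, screen, cfg, seed = 5))
})

test_that("proportional cloning follows crowding distances", {
  # single-member front: every clone is that member
  f1 <- list(fake_candidate(0.8, 0.6, 0.7, 1))
  clones <- clone_proportional(f1, 10)
  expect_true(all(vapply(clones, function(c) c$cost, 0) == f1[[1]]$cost))
  # two members, equal crowding: counts within 1
  f2 <- list(fake_candidate(0.9, 0.5, 0.7, 1), fake_candidate(0.5, 0.9, 0.7, 2))
  counts <- table(vapply(clone_proportional(f2, 11), `[[`, 0, "cost"))
  expect_lte(abs(diff(as.numeric(counts))), 1)
  # four-point front against the independent crowding oracle
  front <- list(fake_candidate(0.95, 0.40, 0.7, 1),
                fake_candidate(0.90, 0.55, 0.7, 2),
                fake_candidate(0.70, 0.60, 0.7, 3),
                fake_candidate(0.50, 0.90, 0.7, 4))
  objs <- t(vapply(front, function(c) c$objectives[1:2], numeric(2)))
  d <- crowding_oracle(objs)
  budget <- 12
  expected <- pmax(1, ceiling(budget * d / sum(d)))
  got <- table(factor(vapply(clone_proportional(front, budget), `[[`, 0, "cost"),
                      levels = vapply(front, `[[`, 0, "cost")))
  expect_equal(as.numeric(got), as.numeric(expected))
})

test_that("mutation honors p_m at the extremes and in expectation", {
  cand <- radER:::new_candidate(1, 0.1, c(TRUE, FALSE, TRUE, FALSE))
  cfg <- automo_config()
  expect_identical(mutate(cand, 0, cfg, seed = 1)$beta, cand$beta)
  expect_identical(mutate(cand, 0, cfg, seed = 1)$cost, cand$cost)
  flipped <- mutate(cand, 1, cfg, seed = 2)
  expect_identical(flipped$beta, !cand$beta)
  # empirical flip rate ~ p_m
  big <- radER:::new_candidate(1, 0.1, rep(TRUE, 1e5))
  m <- mutate(big, 0.1, cfg, seed = 3)
  rate <- mean(m$beta != big$beta)
  expect_gt(rate, 0.095); expect_lt(rate, 0.105)
  # empty mask is repaired
  small <- radER:::new_candidate(1, 0.1, c(TRUE, TRUE))
  m2 <- mutate(small, 1, cfg, seed = 4)
  expect_true(any(m2$beta))
})

test_that("deduplication keeps unique candidates with a 1e-12 tolerance edge", {
  c1 <- radER:::new_candidate(1, 0.1, c(TRUE, FALSE))
  expect_length(deduplicate(rep(list(c1), 5)), 1)
  c2 <- radER:::new_candidate(2, 0.1, c(TRUE, FALSE))
  expect_length(deduplicate(list(c1, c2)), 2)
  c3 <- radER:::new_candidate(1 + 1e-6, 0.1, c(TRUE, FALSE))
  expect_length(deduplicate(list(c1, c3)), 2)
  c4 <- radER:::new_candidate(1 + 1e-14, 0.1, c(TRUE, FALSE))
  expect_length(deduplicate(list(c1, c4)), 1)
})

test_that("archive update equals the brute-force dominance oracle", {
  for (trial in 1:20) {
    pts <- with_seed(trial, matrix(runif(2 * 40), 40, 2))
    pop <- lapply(seq_len(nrow(pts)), function(i) {
      fake_candidate(pts[i, 1], pts[i, 2], runif(1), i)
    })
    arch <- update_archive(list(), pop, archive_max = 100)
    got <- sort(vapply(arch, function(c) c$objectives[["f_sen"]], 0))
    want <- sort(pts[dominance_oracle(pts), 1])
    expect_equal(got, want)
  }
  # spec'd dominance cases
  pts <- rbind(c(0.9, 0.5), c(0.5, 0.9), c(0.6, 0.6))
  expect_length(dominance_oracle(pts), 3)
  pop <- lapply(1:3, function(i) fake_candidate(pts[i, 1], pts[i, 2], 0.5, i))
  expect_length(update_archive(list(), pop, 10), 3)
  pop2 <- list(fake_candidate(0.9, 0.9, 0.5, 1), fake_candidate(0.8, 0.8, 0.5, 2))
  kept <- update_archive(list(), pop2, 10)
  expect_length(kept, 1)
  expect_equal(kept[[1]]$objectives[["f_sen"]], 0.9)
  # overflow truncates by descending AUC
  flat <- lapply(1:6, function(i) fake_candidate(0.5 + i / 100, 0.9 - i / 100,
                                                 i / 10, i))
  trunc <- update_archive(list(), flat, archive_max = 3)
  expect_setequal(vapply(trunc, function(c) c$objectives[["auc"]], 0),
                  c(0.4, 0.5, 0.6))
})

test_that("full training run: dominance-free archive, elitism, determinism", {
  fm <- gaussian_fm(n_per_class = 15, p = 10, d = 1.2, seed = 8,
                    informative = 1:3)
  cfg <- tiny_automo(seed = 21, generations = 5)
  arch <- train_automo(fm, cfg)
  objs <- t(vapply(arch$models, function(c) c$objectives[1:2], numeric(2)))
  expect_setequal(dominance_oracle(objs), seq_len(nrow(objs)))
  log <- arch$generation_log
  expect_true(all(diff(log$best_sen) >= 0))
  expect_true(all(diff(log$best_spe) >= 0))
  expect_true(all(diff(log$hypervolume) >= -1e-12))
  arch2 <- train_automo(fm, cfg)
  expect_identical(lapply(arch$models, `[[`, "objectives"),
                   lapply(arch2$models, `[[`, "objectives"))
  # refit models predict on the training matrix
  probs <- predict_archive(arch, fm)
  expect_equal(dim(probs), c(30, length(arch$models)))
  expect_true(all(probs >= 0 & probs <= 1))
})

test_that("max_generations 0 returns the non-dominated initial population", {
  fm <- gaussian_fm(n_per_class = 10, p = 6, d = 1, seed = 9)
  cfg <- tiny_automo(seed = 31, generations = 0)
  arch <- train_automo(fm, cfg)
  expect_gt(length(arch$models), 0)
  expect_equal(nrow(arch$generation_log), 0)
  objs <- t(vapply(arch$models, function(c) c$objectives[1:2], numeric(2)))
  expect_setequal(dominance_oracle(objs), seq_len(nrow(objs)))
})

test_that("strongly separable data reaches a perfect archive member", {
  fm <- gaussian_fm(n_per_class = 12, p = 4, d = 8, seed = 10)
  arch <- train_automo(fm, tiny_automo(seed = 41, generations = 3))
  objs <- t(vapply(arch$models, function(c) c$objectives[1:2], numeric(2)))
  expect_true(any(objs[, 1] == 1 & objs[, 2] == 1))
})
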