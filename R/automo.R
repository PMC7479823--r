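# Joint feature-subset + SVM-hyperparameter search by an iterative
# multi-objective immune algorithm (initialization, proportional
# cloning, mutation, deduplication, non-dominated archive update,
# termination at a generation cap), with pooled 5-fold CV sensitivity /
# specificity as the objective pair and AUC as reliability tie-breaker.

#' Training configuration for the multi-objective search
#'
#' Defaults are sized for desk-scale cohorts (tens of patients): the
#' paper-scale algorithm structure with population and iteration counts
#' chosen for runtime, and the usual log-scale SVM grid bounds.
#'
#' @param n_pop initial population size.
#' @param clone_budget clones allocated per generation.
#' @param p_m per-bit / per-parameter mutation probability.
#' @param max_generations generation cap (termination criterion).
#' @param archive_max maximum Pareto-archive size.
#' @param cost_range,gamma_range log-uniform sampling bounds for the
#'   SVM cost C and RBF width gamma.
#' @param n_folds CV folds (default 5).
#' @param seed search seed; `fold_seed` (CV partition) derives from it
#'   when `NULL` so folds stay fixed across all candidates.
#' @param fold_seed optional explicit CV seed.
#' @return list of class `automo_config`.
#' @export
automo_config <- function(n_pop = 40L, clone_budget = 40L, p_m = 0.1,
                          max_generations = 50L, archive_max = 20L,
                          cost_range = c(2^-5, 2^15),
                          gamma_range = c(2^-15, 2^3),
                          n_folds = 5L, seed = 1L, fold_seed = NULL) {
  if (!is_count(n_pop) || n_pop < 2)
    rader_abort("n_pop must be >= 2", "config")
  if (!is_number(p_m) || p_m < 0 || p_m > 1)
    rader_abort("p_m must lie in [0, 1]", "config")
  if (!is_count(max_generations))
    rader_abort("max_generations must be a non-negative integer", "config")
  if (any(cost_range <= 0) || any(gamma_range <= 0))
    rader_abort("cost/gamma bounds must be positive", "config")
  structure(list(n_pop = as.integer(n_pop),
                 clone_budget = as.integer(clone_budget), p_m = p_m,
                 max_generations = as.integer(max_generations),
                 archive_max = as.integer(archive_max),
                 cost_range = sort(cost_range),
                 gamma_range = sort(gamma_range),
                 n_folds = as.integer(n_folds),
                 seed = as.integer(seed), fold_seed = fold_seed),
            class = "automo_config")
}

new_candidate <- function(cost, gamma, beta) {
  if (!any(beta)) rader_abort("candidate must include >= 1 feature", "config")
  list(cost = cost, gamma = gamma, beta = beta, objectives = NULL)
}

candidate_key <- function(cand) {
  paste(paste(as.integer(cand$beta), collapse = ""),
        sprintf("%.12e", cand$cost), sprintf("%.12e", cand$gamma))
}

#' Stratified cross-validation fold assignment
#'
#' @param label good/poor factor.
#' @param k number of folds.
#' @param fold_seed integer seed fixing the partition.
#' @return integer fold id per sample; errors if any fold's training
#'   part would lack a class.
#' @export
make_cv_folds <- function(label, k = 5L, fold_seed = 1L) {
  label <- as.character(label)
  folds <- integer(length(label))
  with_seed(fold_seed, {
    for (cl in unique(label)) {
      idx <- which(label == cl)
      folds[idx] <- (seq_along(idx) - 1L) %% k + 1L
      folds[idx] <- folds[idx][sample.int(length(idx))]
    }
  })
  for (f in seq_len(k)) {
    tr <- label[folds != f]
    if (length(unique(tr)) < 2)
      rader_abort(sprintf("fold %d training part lacks a class", f),
                  "stratification")
  }
  folds
}

#' Evaluate one candidate by pooled stratified k-fold CV
#'
#' Fits the RBF-SVM (with in-fold Platt calibration) on each fold's
#' training part restricted to the candidate's feature subset, predicts
#' held-out probabilities, pools them, and scores sensitivity (good
#' positive, threshold 0.5), specificity, and rank-based AUC.
#'
#' @param cand candidate (`cost`, `gamma`, `beta`).
#' @param data training [feature_matrix()].
#' @param folds fold assignment from [make_cv_folds()].
#' @return the candidate with `objectives = c(f_sen, f_spe, auc)`.
#' @export
evaluate_candidate <- function(cand, data, folds) {
  x <- data$x[, cand$beta, drop = FALSE]
  prob <- numeric(nrow(x))
  for (f in sort(unique(folds))) {
    tr <- folds != f
    model <- svm_train(x[tr, , drop = FALSE], data$label[tr],
                       cand$cost, cand$gamma)
    prob[!tr] <- svm_prob(model, x[!tr, , drop = FALSE])
  }
  good <- data$label == "good"
  pred_good <- prob >= 0.5
  sen <- sum(pred_good & good) / sum(good)
  spe <- sum(!pred_good & !good) / sum(!good)
  cand$objectives <- c(f_sen = sen, f_spe = spe,
                       auc = rank_auc(prob, good))
  cand
}

rank_auc <- function(scores, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0)
    rader_abort("AUC undefined with a single class", "metric")
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Hybrid population initialization
#'
#' Half the masks are random subsets of the top screen-ranked features
#' (random subset sizes), half are uniformly random; SVM parameters are
#' sampled log-uniformly within bounds.
#'
#' @param n_pop population size (>= 2).
#' @param screen [t_screen()] result over the candidate features.
#' @param config [automo_config()].
#' @param seed integer seed.
#' @return list of candidates.
#' @export
initialize_population <- function(n_pop, screen, config, seed) {
  n_feat <- nrow(screen)
  top_pool <- order(screen$p)[seq_len(min(n_feat, 20L))]
  sample_alpha <- function() {
    c(exp(runif(1, log(config$cost_range[1]), log(config$cost_range[2]))),
      exp(runif(1, log(config$gamma_range[1]), log(config$gamma_range[2]))))
  }
  with_seed(seed, {
    lapply(seq_len(n_pop), function(i) {
      beta <- rep(FALSE, n_feat)
      if (i <= ceiling(n_pop / 2)) {
        size <- sample.int(length(top_pool), 1)
        beta[sample(top_pool, size)] <- TRUE
      } else {
        beta <- runif(n_feat) < 0.5
        if (!any(beta)) beta[sample.int(n_feat, 1)] <- TRUE
      }
      a <- sample_alpha()
      new_candidate(a[1], a[2], beta)
    })
  })
}

# crowding distance on the (f_sen, f_spe) plane; boundary members get
# the maximum finite distance + 1 so they attract the most clones
crowding_distance <- function(objs) {
  n <- nrow(objs)
  if (n == 1) return(1)
  d <- numeric(n)
  for (m in 1:2) {
    o <- order(objs[, m])
    rng <- objs[o[n], m] - objs[o[1], m]
    d[o[1]] <- Inf; d[o[n]] <- Inf
    if (rng > 0 && n > 2) {
      for (i in 2:(n - 1))
        d[o[i]] <- d[o[i]] + (objs[o[i + 1], m] - objs[o[i - 1], m]) / rng
    }
  }
  finite <- d[is.finite(d)]
  cap <- if (length(finite)) max(finite) + 1 else 1
  d[!is.finite(d)] <- cap
  if (all(d == 0)) d[] <- 1
  d
}

#' Proportional cloning of the archive front
#'
#' Each member receives `ceiling(budget * d_i / sum(d))` clones, where
#' `d_i` is its crowding distance on (f_sen, f_spe); every member is
#' cloned at least once.
#'
#' @param front list of evaluated candidates.
#' @param clone_budget total clone budget.
#' @return list of cloned candidates (evaluations kept).
#' @export
clone_proportional <- function(front, clone_budget) {
  if (length(front) == 0) rader_abort("empty front", "config")
  objs <- t(vapply(front, function(c) c$objectives[1:2], numeric(2)))
  d <- crowding_distance(objs)
  counts <- pmax(1L, ceiling(clone_budget * d / sum(d)))
  unlist(lapply(seq_along(front), function(i) {
    rep(front[i], counts[i])
  }), recursive = FALSE)
}

#' Mutate a candidate
#'
#' Each feature bit flips with probability `p_m`; cost and gamma are
#' each perturbed multiplicatively by log-normal noise with probability
#' `p_m` (clamped to bounds). A mutation that empties the feature mask
#' has one random bit re-enabled.
#'
#' @param cand candidate.
#' @param p_m mutation probability in `[0, 1]`.
#' @param config [automo_config()] (for the bounds).
#' @param seed optional seed; by default the caller's RNG stream is
#'   used.
#' @return mutated candidate (objectives cleared if anything changed).
#' @export
mutate <- function(cand, p_m, config = automo_config(), seed = NULL) {
  run <- function() {
    flip <- runif(length(cand$beta)) < p_m
    beta <- xor(cand$beta, flip)
    if (!any(beta)) beta[sample.int(length(beta), 1)] <- TRUE
    cost <- cand$cost; gamma <- cand$gamma
    if (runif(1) < p_m)
      cost <- min(max(cost * exp(rnorm(1, 0, 0.8)), config$cost_range[1]),
                  config$cost_range[2])
    if (runif(1) < p_m)
      gamma <- min(max(gamma * exp(rnorm(1, 0, 0.8)), config$gamma_range[1]),
                   config$gamma_range[2])
    changed <- any(beta != cand$beta) || cost != cand$cost ||
      gamma != cand$gamma
    out <- new_candidate(cost, gamma, beta)
    if (!changed) out$objectives <- cand$objectives
    out
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Remove duplicate candidates
#'
#' Candidates with identical feature masks and parameters equal within
#' 1e-12 (relative) collapse to one.
#'
#' @param pop list of candidates.
#' @return deduplicated list.
#' @export
deduplicate <- function(pop) {
  if (length(pop) < 2) return(pop)
  keep <- rep(TRUE, length(pop))
  near <- function(a, b) abs(a - b) <= 1e-12 * max(1, abs(a), abs(b))
  for (i in seq_along(pop)) {
    if (!keep[i]) next
    for (j in seq_len(i - 1L)) {
      if (!keep[j]) next
      if (identical(pop[[i]]$beta, pop[[j]]$beta) &&
          near(pop[[i]]$cost, pop[[j]]$cost) &&
          near(pop[[i]]$gamma, pop[[j]]$gamma)) {
        keep[i] <- FALSE
        break
      }
    }
  }
  pop[keep]
}

# a dominates b on (f_sen, f_spe): >= in both, > in at least one
dominates <- function(a, b) {
  all(a[1:2] >= b[1:2]) && any(a[1:2] > b[1:2])
}

pareto_front_idx <- function(objs) {
  n <- nrow(objs)
  nondom <- rep(TRUE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && dominates(objs[j, ], objs[i, ])) {
        nondom[i] <- FALSE
        break
      }
    }
  }
  which(nondom)
}

#' Update the Pareto archive
#'
#' Merges the archive with a population of evaluated candidates,
#' deduplicates, keeps the non-dominated (rank-0) front on
#' (f_sen, f_spe), and truncates to `archive_max` members by descending
#' AUC if the front overflows.
#'
#' @param archive list of evaluated candidates (possibly empty).
#' @param pop list of evaluated candidates.
#' @param archive_max maximum archive size.
#' @return list of candidates forming the new archive.
#' @export
update_archive <- function(archive, pop, archive_max = 20L) {
  all_c <- deduplicate(c(archive, pop))
  objs <- t(vapply(all_c, function(c) c$objectives[1:2], numeric(2)))
  front <- all_c[pareto_front_idx(objs)]
  if (length(front) > archive_max) {
    auc <- vapply(front, function(c) c$objectives["auc"], numeric(1))
    front <- front[order(-auc)[seq_len(archive_max)]]
  }
  front
}

hypervolume2d <- function(objs) {
  # dominated area above the origin reference point
  o <- objs[order(objs[, 2], objs[, 1]), , drop = FALSE]
  hv <- 0; prev_spe <- 0
  for (i in seq_len(nrow(o))) {
    sen_max <- max(objs[objs[, 2] >= o[i, 2], 1])
    hv <- hv + sen_max * (o[i, 2] - prev_spe)
    prev_spe <- o[i, 2]
  }
  hv
}

#' Train the Pareto-optimal model set
#'
#' Runs the six-step immune loop (initialize, clone, mutate, dedupe,
#' archive update, terminate at `max_generations`), then refits every
#' archive member's SVM on the full training arm with its own
#' parameters and feature subset.
#'
#' @param data training [feature_matrix()] with both classes.
#' @param config an [automo_config()].
#' @return object of class `pareto_archive`: `models` (each with
#'   `cost`, `gamma`, `beta`, `objectives`, fitted `fit`),
#'   `feature_names`, `fold_seed`, `generation_log`.
#' @export
train_automo <- function(data, config = automo_config()) {
  if (length(unique(data$label)) < 2)
    rader_abort("training data needs both classes", "class_balance")
  seeds <- derive_seeds(config$seed, 3)
  fold_seed <- config$fold_seed %||% seeds[1]
  folds <- make_cv_folds(data$label, config$n_folds, fold_seed)
  screen <- t_screen(data)
  cache <- new.env(parent = emptyenv())
  eval_pop <- function(pop) {
    lapply(pop, function(cand) {
      if (!is.null(cand$objectives)) return(cand)
      key <- candidate_key(cand)
      hit <- cache[[key]]
      if (!is.null(hit)) {
        cand$objectives <- hit
        return(cand)
      }
      cand <- evaluate_candidate(cand, data, folds)
      cache[[key]] <- cand$objectives
      cand
    })
  }
  pop <- eval_pop(initialize_population(config$n_pop, screen, config,
                                        seeds[2]))
  archive <- update_archive(list(), pop, config$archive_max)
  log <- list()
  with_seed(seeds[3], {
    gen <- 0L
    while (gen < config$max_generations) {
      gen <- gen + 1L
      clones <- clone_proportional(archive, config$clone_budget)
      mutated <- lapply(clones, mutate, p_m = config$p_m, config = config)
      mutated <- eval_pop(deduplicate(mutated))
      archive <- update_archive(archive, mutated, config$archive_max)
      objs <- t(vapply(archive, function(c) c$objectives[1:2], numeric(2)))
      log[[gen]] <- data.frame(generation = gen, front_size = length(archive),
                               hypervolume = hypervolume2d(objs),
                               best_sen = max(objs[, 1]),
                               best_spe = max(objs[, 2]))
    }
  })
  models <- lapply(archive, function(cand) {
    cand$fit <- svm_train(data$x[, cand$beta, drop = FALSE], data$label,
                          cand$cost, cand$gamma)
    cand
  })
  structure(list(models = models, feature_names = colnames(data$x),
                 fold_seed = fold_seed, config = config,
                 generation_log = if (length(log)) do.call(rbind, log)
                                  else data.frame()),
            class = "pareto_archive")
}

#' @export
print.pareto_archive <- function(x, ...) {
  objs <- t(vapply(x$models, function(c) c$objectives, numeric(3)))
  cat(sprintf("<pareto_archive> %d models; sen %.2f-%.2f, spe %.2f-%.2f, best AUC %.3f\n",
              length(x$models), min(objs[, 1]), max(objs[, 1]),
              min(objs[, 2]), max(objs[, 2]), max(objs[, 3])))
  invisible(x)
}

#' Per-model good-class probabilities for new samples
#'
#' @param archive a [train_automo()] result.
#' @param fm feature matrix over the archive's feature columns.
#' @return matrix, samples x models, of P(good).
#' @export
predict_archive <- function(archive, fm) {
  x <- fm$x[, archive$feature_names, drop = FALSE]
  matrix(vapply(archive$models, function(cand) {
    svm_prob(cand$fit, x[, cand$beta, drop = FALSE])
  }, numeric(nrow(x))), nrow = nrow(x))
}
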