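# Fixture builders and independent oracles shared across test files.
# Oracles deliberately re-derive quantities by brute force / recursion,
# independent of the implementation paths they check.

# -- fixtures ---------------------------------------------------------------

circle_scan <- function(radius = 10, side = 2 * radius + 9, value = NULL,
                        spacing = c(1, 1), seed = 42) {
  ctr <- (side - 1) / 2
  rows <- matrix(seq_len(side) - 1, side, side)
  cols <- t(rows)
  mask <- (rows - ctr)^2 + (cols - ctr)^2 <= radius^2
  img <- if (is.null(value)) {
    with_seed(seed, matrix(100 + 10 * rnorm(side^2), side, side))
  } else matrix(value, side, side)
  roi_scan(img, mask, spacing = spacing)
}

rect_scan <- function(w = 4, h = 2, side = 12, value = NULL, seed = 7) {
  mask <- matrix(FALSE, side, side)
  mask[3:(2 + h), 3:(2 + w)] <- TRUE
  img <- if (is.null(value)) {
    with_seed(seed, matrix(50 + 5 * rnorm(side^2), side, side))
  } else matrix(value, side, side)
  roi_scan(img, mask)
}

random_scan <- function(side = 24, seed = 1, examination = "pre") {
  with_seed(seed, {
    ctr <- (side - 1) / 2
    rows <- matrix(seq_len(side) - 1, side, side)
    cols <- t(rows)
    mask <- ((rows - ctr) / (side / 3))^2 + ((cols - ctr) / (side / 4))^2 <= 1
    img <- matrix(100 + 15 * rnorm(side^2), side, side)
    roi_scan(img, mask, examination = examination)
  })
}

tiny_spec <- function(effect_size = 2, seed = 1, side = 48) {
  cohort_spec(n_train = 12, n_val = 8,
              train_counts = c(true_pd = 5, pseudoprogression = 2, sd_pr = 5),
              val_counts = c(true_pd = 4, pseudoprogression = 1, sd_pr = 3),
              effect_size = effect_size, image_side = side, seed = seed)
}

tiny_automo <- function(seed = 1, generations = 4) {
  automo_config(n_pop = 12, clone_budget = 12, max_generations = generations,
                archive_max = 12, seed = seed)
}

gaussian_fm <- function(n_per_class = 20, p = 6, d = 2, seed = 1,
                        informative = 1:2) {
  with_seed(seed, {
    x <- matrix(rnorm(2 * n_per_class * p), 2 * n_per_class, p,
                dimnames = list(NULL, paste0("f", seq_len(p))))
    lab <- rep(c("good", "poor"), each = n_per_class)
    x[lab == "good", informative] <- x[lab == "good", informative] + d
    feature_matrix(x, lab)
  })
}

# -- oracles ----------------------------------------------------------------

# standardized central moments by direct formula
moment_oracle <- function(v) {
  m <- mean(v); n <- length(v)
  ck <- function(k) sum((v - m)^k) / n
  list(skewness = ck(3) / ck(2)^(3 / 2), kurtosis = ck(4) / ck(2)^2)
}

# recursive pairwise Dempster combination of weight-discounted masses;
# masses per model: m({good}) = w*p1, m({poor}) = w*p2, m(frame) = 1-w
er_oracle <- function(p_good, omega) {
  combine <- function(m1, m2) {
    conflict <- m1[1] * m2[2] + m1[2] * m2[1]
    norm <- 1 - conflict
    c(g = (m1[1] * m2[1] + m1[1] * m2[3] + m1[3] * m2[1]) / norm,
      p = (m1[2] * m2[2] + m1[2] * m2[3] + m1[3] * m2[2]) / norm,
      t = (m1[3] * m2[3]) / norm)
  }
  masses <- lapply(seq_along(omega), function(j) {
    c(omega[j] * p_good[j], omega[j] * (1 - p_good[j]), 1 - omega[j])
  })
  m <- Reduce(combine, masses)
  unname(c(m[1], m[2]) / (m[1] + m[2]))
}

# brute-force strict-Pareto non-dominated subset on (f_sen, f_spe)
dominance_oracle <- function(objs) {
  n <- nrow(objs)
  keep <- vapply(seq_len(n), function(i) {
    !any(vapply(seq_len(n), function(j) {
      j != i && all(objs[j, ] >= objs[i, ]) && any(objs[j, ] > objs[i, ])
    }, logical(1)))
  }, logical(1))
  which(keep)
}

# exhaustive pair-counting AUC (ties count half)
auc_oracle <- function(scores, positive) {
  pos <- scores[positive]; neg <- scores[!positive]
  total <- 0
  for (a in pos) for (b in neg)
    total <- total + if (a > b) 1 else if (a == b) 0.5 else 0
  total / (length(pos) * length(neg))
}

# crowding distances on a 2-objective front, written independently
crowding_oracle <- function(objs) {
  n <- nrow(objs)
  d <- numeric(n)
  for (m in 1:2) {
    o <- order(objs[, m])
    rng <- diff(range(objs[, m]))
    d[o[c(1, n)]] <- Inf
    if (rng > 0) for (i in 2:(n - 1))
      d[o[i]] <- d[o[i]] + (objs[o[i + 1], m] - objs[o[i - 1], m]) / rng
  }
  cap <- max(d[is.finite(d)], 0) + 1
  d[!is.finite(d)] <- cap
  d
}

fake_candidate <- function(sen, spe, auc, id) {
  list(cost = 1 + id, gamma = 0.1, beta = c(TRUE, rep(FALSE, 3)),
       objectives = c(f_sen = sen, f_spe = spe, auc = auc))
}
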