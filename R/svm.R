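# RBF-kernel support vector classifier with Platt probability
# calibration, built on the package's SMO dual solver (src/svm.cpp).

rbf_kernel <- function(x, z = x, gamma) {
  xn <- rowSums(x^2)
  zn <- rowSums(z^2)
  d2 <- outer(xn, zn, `+`) - 2 * tcrossprod(x, z)
  exp(-gamma * pmax(d2, 0))
}

#' Fit an RBF-kernel SVM
#'
#' Labels are the package's `good`/`poor` factor; `good` is the positive
#' class. Returns the fitted dual solution plus a Platt sigmoid mapping
#' decision values to P(good), fitted on the training decision values.
#'
#' @param x numeric matrix (rows = samples).
#' @param label factor/character of `good`/`poor`, both present.
#' @param cost soft-margin cost C > 0.
#' @param gamma RBF kernel width > 0.
#' @return object of class `rader_svm`.
#' @export
svm_train <- function(x, label, cost, gamma) {
  y <- ifelse(as.character(label) == "good", 1L, -1L)
  if (length(unique(y)) < 2)
    rader_abort("SVM training requires both classes", "class_balance")
  if (!is_number(cost) || cost <= 0 || !is_number(gamma) || gamma <= 0)
    rader_abort("cost and gamma must be positive", "config")
  x <- as.matrix(x)
  K <- rbf_kernel(x, gamma = gamma)
  fit <- svm_smo_fit(K, y, cost)
  dec <- as.numeric(K %*% (fit$alpha * y) + fit$b)
  model <- structure(list(x = x, y = y, alpha = fit$alpha, b = fit$b,
                          cost = cost, gamma = gamma,
                          objective = fit$objective,
                          platt = platt_fit(dec, y)),
                     class = "rader_svm")
  model
}

#' SVM decision values
#'
#' @param model a `rader_svm`.
#' @param newx matrix of samples.
#' @return numeric decision values (positive = `good` side).
#' @export
svm_decision <- function(model, newx) {
  K <- rbf_kernel(as.matrix(newx), model$x, model$gamma)
  as.numeric(K %*% (model$alpha * model$y) + model$b)
}

#' Calibrated class probabilities
#'
#' @param model a `rader_svm`.
#' @param newx matrix of samples.
#' @return numeric vector of P(good), in (0, 1), with
#'   P(good) + P(poor) = 1 by construction.
#' @export
svm_prob <- function(model, newx) {
  platt_apply(model$platt, svm_decision(model, newx))
}

# Platt's sigmoid fit p(y=1|f) = 1/(1+exp(A f + B)), Newton's method
# with the regularized targets of Lin, Lin & Weng (2007).
platt_fit <- function(dec, y, max_iter = 100, tol = 1e-10) {
  n1 <- sum(y > 0); n0 <- sum(y < 0)
  hi <- (n1 + 1) / (n1 + 2)
  lo <- 1 / (n0 + 2)
  t <- ifelse(y > 0, hi, lo)
  A <- 0; B <- log((n0 + 1) / (n1 + 1))
  fval <- function(A, B) {
    z <- A * dec + B
    sum(ifelse(z >= 0, t * z + log1p(exp(-z)), (t - 1) * z + log1p(exp(z))))
  }
  fv <- fval(A, B)
  for (it in seq_len(max_iter)) {
    z <- A * dec + B
    p <- ifelse(z >= 0, exp(-z) / (1 + exp(-z)), 1 / (1 + exp(z)))
    q <- 1 - p
    d1A <- sum(dec * (t - p)); d1B <- sum(t - p)
    w <- p * q
    h11 <- sum(dec^2 * w) + 1e-12
    h22 <- sum(w) + 1e-12
    h12 <- sum(dec * w)
    det <- h11 * h22 - h12^2
    if (abs(d1A) < tol && abs(d1B) < tol) break
    dA <- -(h22 * d1A - h12 * d1B) / det
    dB <- -(h11 * d1B - h12 * d1A) / det
    step <- 1
    repeat {
      A2 <- A + step * dA; B2 <- B + step * dB
      f2 <- fval(A2, B2)
      if (f2 < fv + 1e-4 * step * (d1A * dA + d1B * dB) || step < 1e-10) {
        A <- A2; B <- B2; fv <- f2
        break
      }
      step <- step / 2
    }
  }
  list(A = A, B = B)
}

platt_apply <- function(platt, dec) {
  z <- platt$A * dec + platt$B
  ifelse(z >= 0, exp(-z) / (1 + exp(-z)), 1 / (1 + exp(z)))
}
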