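# Independent oracles and tiny fixture builders used across the suite.

# central finite-difference gradient of the batch MSE loss, parameter by
# parameter -- deliberately naive and independent of bp_gradient()
fd_gradient <- function(weights, X, y, h = 1e-6) {
  loss <- function(w) {
    r <- bp_forward(w, X) - matrix(y, ncol = nrow(w$W2))
    mean(rowSums(r^2))
  }
  out <- weights
  for (nm in c("W1", "b1", "W2", "b2")) {
    g <- weights[[nm]]
    for (i in seq_along(g)) {
      wp <- weights; wp[[nm]][i] <- wp[[nm]][i] + h
      wm <- weights; wm[[nm]][i] <- wm[[nm]][i] - h
      g[i] <- (loss(wp) - loss(wm)) / (2 * h)
    }
    out[[nm]] <- g
  }
  out
}

# term-by-term quadratic evaluator, independent of predict_quadratic()
naive_quadratic_eval <- function(model, x) {
  v <- model$intercept + sum(model$linear * x) + sum(model$pure_quadratic * x^2)
  p <- 0
  for (i in seq_len(model$k - 1)) {
    for (j in (i + 1):model$k) {
      p <- p + 1
      v <- v + model$interaction[p] * x[i] * x[j]
    }
  }
  v
}

# loop-based metric oracles
loop_mse <- function(t, p) {
  s <- 0
  for (i in seq_along(t)) s <- s + (t[i] - p[i])^2
  s / length(t)
}

random_arch <- function(seed) {
  withr::with_seed(seed, bp_arch(sample(1:4, 1), sample(1:5, 1), 1L))
}

# a tiny two-factor dataset from a known quadratic, for fast CV tests
tiny_dataset <- function(seed = 1, noise_sd = 0.5, n_center = 3) {
  factors <- list(factor_spec("a", "A", "u", 0, 1),
                  factor_spec("b", "B", "u", 0, 1))
  design <- build_ccd(factors, alpha = 1.5, n_center = n_center)
  truth <- 85 - 2 * design$coded[, 1]^2 - 3 * design$coded[, 2]^2 +
    1.5 * design$coded[, 1]
  y <- truth + withr::with_seed(seed, stats::rnorm(length(truth), 0, noise_sd))
  ccd_table(design$coded, factors, observed = y)
}

fast_train <- function(...) train_config(max_epochs = 200, ...)
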