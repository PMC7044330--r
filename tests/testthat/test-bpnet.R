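test_that("min-max scaler round-trips exactly and hits the interval ends", {
  withr::with_seed(3, {
    X <- matrix(runif(40, -5, 40), 10, 4)
    s <- fit_scaler(X)
    Z <- scaler_apply(s, X)
    expect_equal(apply(Z, 2, min), rep(-1, 4), ignore_attr = TRUE)
    expect_equal(apply(Z, 2, max), rep(1, 4), ignore_attr = TRUE)
    expect_equal(scaler_invert(s, Z), X, tolerance = 1e-12)
  })
  # coded CCD columns with axial distance 2 map -2 -> -1 and 2 -> 1
  t1 <- load_table1()
  s <- fit_scaler(t1$coded)
  Z <- scaler_apply(s, t1$coded)
  expect_equal(range(Z), c(-1, 1))
  expect_equal(Z[17, 1], -1, ignore_attr = TRUE)  # the -2 axial run of factor 1
  expect_error(fit_scaler(matrix(1, 5, 2)), "degenerate scaler")
})

test_that("weight initialization is seed-reproducible with consistent shapes", {
  arch <- bp_arch(4, 3, 1)
  w1 <- init_weights(arch, seed = 42)
  w2 <- init_weights(arch, seed = 42)
  expect_identical(w1, w2)
  expect_false(identical(w1, init_weights(arch, seed = 43)))
  expect_equal(dim(w1$W1), c(3, 4))
  expect_length(w1$b1, 3)
  expect_equal(dim(w1$W2), c(1, 3))
  expect_length(w1$b2, 1)
})

test_that("forward pass matches a hand-evaluated 1-1-1 network", {
  w <- structure(list(W1 = matrix(0.7), b1 = -0.2, W2 = matrix(1.3), b2 = 0.4),
                 class = "bp_weights")
  x <- 0.9
  expect_equal(bp_forward(w, matrix(x)), matrix(1.3 * tanh(0.7 * 0.9 - 0.2) + 0.4),
               tolerance = 1e-12)
  # tansig form 2/(1+exp(-2z)) - 1 equals tanh(z)
  z <- seq(-3, 3, 0.5)
  expect_equal(2 / (1 + exp(-2 * z)) - 1, tanh(z), tolerance = 1e-12)
  # all-zero weights: output is the output bias
  w0 <- structure(list(W1 = matrix(0, 2, 3), b1 = c(0, 0),
                       W2 = matrix(0, 1, 2), b2 = 0.33), class = "bp_weights")
  expect_equal(as.numeric(bp_forward(w0, matrix(rnorm(6), 2, 3))), c(0.33, 0.33))
  expect_error(bp_forward(w0, matrix(1, 1, 2)), "dimension")
})

test_that("backprop gradient agrees with central finite differences", {
  worst <- 0
  for (s in 1:50) {
    arch <- random_arch(1000 + s)
    w <- init_weights(arch, seed = s)
    withr::with_seed(2000 + s, {
      X <- matrix(runif(6 * arch$n_in, -1, 1), 6, arch$n_in)
      y <- runif(6, -1, 1)
    })
    g <- bp_gradient(w, X, y)
    fd <- fd_gradient(w, X, y)
    for (nm in c("W1", "b1", "W2", "b2")) {
      denom <- pmax(abs(fd[[nm]]), 1e-3)
      worst <- max(worst, max(abs(g[[nm]] - fd[[nm]]) / denom))
    }
  }
  expect_lt(worst, 1e-5)
})

test_that("gradient is zero at zero residual and invariant to duplication", {
  arch <- bp_arch(3, 2, 1)
  w <- init_weights(arch, seed = 5)
  X <- matrix(withr::with_seed(6, runif(12, -1, 1)), 4, 3)
  y <- as.numeric(bp_forward(w, X))
  g <- bp_gradient(w, X, y)
  expect_equal(grad_norm <- sqrt(sum(unlist(g)^2)), 0, tolerance = 1e-14)
  y2 <- withr::with_seed(7, runif(4, -1, 1))
  g1 <- bp_gradient(w, X, y2)
  g2 <- bp_gradient(w, rbind(X, X), c(y2, y2))
  expect_equal(g1, g2, tolerance = 1e-13)
})

test_that("training reduces MSE and honors the stopping contracts", {
  withr::with_seed(8, {
    X <- matrix(runif(80, -1, 1), 20, 4)
    y <- 0.3 * X[, 1] - 0.5 * X[, 3]   # noiseless, well within network capacity
  })
  arch <- bp_arch(4, 3, 1)
  for (alg in c("gd", "gdm", "gda", "gdx", "lm")) {
    rec <- bp_train(arch, X, y, train_config(algorithm = alg, max_epochs = 300,
                                             seed = 2))
    w0 <- init_weights(arch, 2)
    r0 <- as.numeric(bp_forward(w0, X)) - y
    expect_lt(rec$final_mse, mean(r0^2))
    expect_equal(rec$final_mse, rec$epoch_mse[length(rec$epoch_mse)])
  }
  # an immediately-satisfied goal stops after one epoch
  rec <- bp_train(arch, X, y, train_config(goal_mse = 1e6, seed = 2))
  expect_equal(rec$stop_reason, "goal")
  expect_length(rec$epoch_mse, 1)
  # determinism: identical config twice gives identical records
  cfg <- train_config(algorithm = "gdx", max_epochs = 50, seed = 9)
  expect_identical(bp_train(arch, X, y, cfg), bp_train(arch, X, y, cfg))
})

test_that("gdx learning rate stays positive and grows only after improvement", {
  withr::with_seed(11, {
    X <- matrix(runif(60, -1, 1), 15, 4)
    y <- tanh(X[, 1]) - 0.4 * X[, 2]
  })
  cfg <- train_config(algorithm = "gdx", max_epochs = 400, seed = 3)
  rec <- bp_train(bp_arch(4, 3, 1), X, y, cfg)
  expect_true(all(rec$learning_rates > 0))
  grew <- which(diff(rec$learning_rates) > 0) + 1
  improved <- which(diff(rec$epoch_mse) < 0) + 1
  expect_true(all(grew %in% improved))
})

test_that("divergent training raises an epoch-stamped error", {
  withr::with_seed(12, {
    X <- matrix(runif(40, -1, 1), 10, 4)
    y <- X[, 1]
  })
  expect_error(
    bp_train(bp_arch(4, 3, 1), X, y,
             train_config(algorithm = "gd", learning_rate = 1e6, seed = 1)),
    "divergence error at epoch")
})

test_that("wider networks can fit the melon data better than width 3", {
  t1 <- load_table1()
  better <- 0
  for (s in 1:5) {
    cfg <- train_config(algorithm = "gdx", max_epochs = 2000, seed = 100 * s)
    m3 <- fit_bp_surrogate(t1, 3, cfg, restarts = 2)
    m8 <- fit_bp_surrogate(t1, 8, cfg, restarts = 2)
    if (min(m8$restart_mse) < min(m3$restart_mse)) better <- better + 1
  }
  expect_gte(better, 3)  # capacity helps in most seeds
})

test_that("a fitted surrogate survives the JSON round trip", {
  t1 <- load_table1()
  net <- fit_bp_surrogate(t1, 3, fast_train(seed = 4), restarts = 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_bp_net(net, path)
  back <- read_bp_net(path)
  expect_equal(predict(back, t1$coded), predict(net, t1$coded),
               tolerance = 1e-12)
})
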