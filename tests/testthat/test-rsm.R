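test_that("OLS recovers a noiseless quadratic exactly", {
  truth <- quadratic_model(80, c(1, -2, 0.5, 0.3), c(-1, -0.5, -2, -0.8),
                           c(0.2, -0.4, 0.1, 0.6, -0.2, 0.3))
  design <- build_ccd(melon_factors(), alpha = 2, n_center = 7)
  y <- predict_quadratic(truth, design$coded)
  data <- ccd_table(design$coded, design$factors, observed = y)
  fit <- fit_full_quadratic(data)
  expect_equal(fit$intercept, truth$intercept, tolerance = 1e-8)
  expect_equal(fit$linear, truth$linear, tolerance = 1e-8)
  expect_equal(fit$pure_quadratic, truth$pure_quadratic, tolerance = 1e-8)
  expect_equal(fit$interaction, truth$interaction, tolerance = 1e-8)
  expect_equal(fit$r_squared, 1, tolerance = 1e-8)
})

test_that("adding a constant shifts only the intercept; proportion scale divides coefficients", {
  t1 <- load_table1()
  f1 <- fit_full_quadratic(t1)
  shifted <- ccd_table(t1$coded, t1$factors, observed = t1$observed + 5)
  f2 <- fit_full_quadratic(shifted)
  expect_equal(f2$intercept, f1$intercept + 5, tolerance = 1e-8)
  expect_equal(f2$linear, f1$linear, tolerance = 1e-8)
  prop <- ccd_table(t1$coded, t1$factors, observed = t1$observed / 100)
  f3 <- fit_full_quadratic(prop)
  expect_equal(f3$intercept, f1$intercept / 100, tolerance = 1e-10)
  expect_equal(f3$linear, f1$linear / 100, tolerance = 1e-10)
  expect_equal(f3$interaction, f1$interaction / 100, tolerance = 1e-10)
})

test_that("OLS residuals are orthogonal to every design column", {
  t1 <- load_table1()
  fit <- fit_full_quadratic(t1)
  resid <- t1$observed - predict_quadratic(fit, t1$coded)
  X <- t1$coded
  M <- cbind(1, X, X^2,
             X[, 1] * X[, 2], X[, 1] * X[, 3], X[, 1] * X[, 4],
             X[, 2] * X[, 3], X[, 2] * X[, 4], X[, 3] * X[, 4])
  expect_lt(max(abs(crossprod(M, resid))), 1e-8)
})

test_that("prediction matches a term-by-term evaluation oracle", {
  withr::with_seed(31, {
    for (i in 1:10) {
      m <- quadratic_model(runif(1, 50, 90), runif(4, -2, 2), runif(4, -2, 0),
                           runif(6, -1, 1))
      x <- runif(4, -2, 2)
      expect_equal(predict_quadratic(m, x), naive_quadratic_eval(m, x),
                   tolerance = 1e-12)
      expect_equal(predict_quadratic(m, rep(0, 4)), m$intercept)
    }
  })
})

test_that("box-constrained maximization finds analytic and corner optima", {
  # concave separable paraboloid with interior maximum at (1, 0.5, 0.25, 0)
  m <- quadratic_model(90, c(2, 1, 0.5, 0), c(-1, -1, -1, -1), rep(0, 6))
  opt <- maximize_quadratic(m, matrix(c(-2, 2), 2, 4))
  expect_equal(opt$point, c(1, 0.5, 0.25, 0), tolerance = 1e-4)
  expect_equal(opt$value, predict_quadratic(m, c(1, 0.5, 0.25, 0)),
               tolerance = 1e-8)
  # linear model maximizes at a corner
  lin <- quadratic_model(50, c(1, -2, 3, 0.5), rep(0, 4), rep(0, 6))
  opt2 <- maximize_quadratic(lin, matrix(c(-2, 2), 2, 4))
  expect_equal(opt2$point, c(2, -2, 2, 2), tolerance = 1e-6)
  # returned value dominates a fresh grid scan
  withr::with_seed(17, {
    m3 <- quadratic_model(80, runif(4, -1, 1), runif(4, -1.5, -0.2),
                          runif(6, -0.5, 0.5))
    opt3 <- maximize_quadratic(m3, matrix(c(-2, 2), 2, 4))
    G <- as.matrix(expand.grid(replicate(4, seq(-2, 2, 0.5), simplify = FALSE)))
    expect_gte(opt3$value, max(predict_quadratic(m3, G)) - 1e-10)
  })
})

test_that("quadratic models survive the JSON round trip", {
  t1 <- load_table1()
  fit <- fit_full_quadratic(t1)
  path <- withr::local_tempfile(fileext = ".json")
  write_quadratic_json(fit, path)
  back <- read_quadratic_json(path)
  expect_equal(back$intercept, fit$intercept, tolerance = 1e-12)
  expect_equal(predict_quadratic(back, t1$coded),
               predict_quadratic(fit, t1$coded), tolerance = 1e-12)
  tab <- quadratic_coef_table(fit)
  expect_equal(nrow(tab), 15)
})

test_that("degenerate designs are rejected", {
  t1 <- load_table1()
  small <- ccd_table(t1$coded[1:10, ], t1$factors, observed = t1$observed[1:10])
  expect_error(fit_full_quadratic(small), "more runs")
  dup <- ccd_table(t1$coded[c(rep(1, 20), 2:10), ], t1$factors,
                   observed = t1$observed[c(rep(1, 20), 2:10)])
  expect_error(fit_full_quadratic(dup), "singular|rank")
})
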