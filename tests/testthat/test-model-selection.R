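test_that("k-fold partitions are disjoint covers with near-equal sizes", {
  folds <- kfold_indices(31, 10, seed = 1)
  sizes <- sort(vapply(folds, length, 0L))
  expect_equal(unname(sizes), c(rep(3L, 9), 4L))
  expect_setequal(unlist(folds), 1:31)
  expect_identical(kfold_indices(31, 10, seed = 1), kfold_indices(31, 10, seed = 1))
  expect_false(identical(kfold_indices(31, 10, 1), kfold_indices(31, 10, 2)))
  expect_error(kfold_indices(5, 6, 1), "infeasible")
  # leave-one-out boundary
  loo <- kfold_indices(8, 8, 1)
  expect_true(all(vapply(loo, length, 0L) == 1))
})

test_that("cross_validate is deterministic and beats the predict-the-mean baseline on structure", {
  # a smooth four-factor surface observed with little noise: a surrogate that
  # captures the structure must beat the variance-of-target baseline, which is
  # the held-out score of a degenerate predict-the-mean learner
  spec <- sample_surface_spec(seed = 77, noise_sd = 0.5)
  design <- build_ccd(melon_factors(), alpha = 2, n_center = 7)
  data <- generate_dataset(spec, design)
  plan <- cv_plan(k = 5, repeats = 2, seed = 5)
  arch <- bp_arch(4, 3, 1)
  cfg <- fast_train(algorithm = "lm", seed = 1)
  r1 <- cross_validate(arch, cfg, data, plan)
  r2 <- cross_validate(arch, cfg, data, plan)
  expect_identical(r1, r2)
  expect_equal(r1$mean_mse, mean(r1$repeat_mse))
  baseline <- var(data$observed / 100)
  expect_lt(r1$mean_mse, baseline)
})

test_that("every row is held out exactly once per repeat", {
  for (r in 1:3) {
    folds <- kfold_indices(31, 10, seed = 100 + r)
    counts <- table(unlist(folds))
    expect_true(all(counts == 1))
    expect_length(counts, 31)
  }
})

test_that("trainer selection ranks candidates by mean held-out MSE", {
  data <- tiny_dataset(seed = 22, noise_sd = 0.3)
  plan <- cv_plan(k = 4, repeats = 1, seed = 9)
  res <- select_training_function(c("gdx", "lm", "gd"), data, plan,
                                  hidden = 3, config = fast_train(seed = 1))
  mses <- vapply(res, `[[`, 0, "mean_mse")
  expect_true(all(diff(mses) >= 0))
  expect_true(all(is.finite(mses)))
  single <- select_training_function("gdx", data, plan, hidden = 3,
                                     config = fast_train(seed = 1))
  expect_length(single, 1)
  expect_equal(single[[1]]$label, "gdx")
  expect_error(select_training_function(character(0), data, plan),
               "configuration error")
})

test_that("hidden-width selection favors parsimonious widths on a quadratic surface", {
  winners <- integer(0)
  for (s in 1:3) {
    spec <- sample_surface_spec(seed = 300 + s, k = 2, noise_sd = 0.5)
    design <- build_ccd(list(factor_spec("a", "A", "u", 0, 1),
                             factor_spec("b", "B", "u", 0, 1)),
                        alpha = 1.5, n_center = 5)
    data <- generate_dataset(spec, design)
    res <- select_hidden_size(c(1, 2, 4, 8, 12), "lm", data,
                              cv_plan(k = 4, repeats = 2, seed = s),
                              config = fast_train(seed = 1))
    winners <- c(winners, as.integer(res[[1]]$label))
    mses <- vapply(res, `[[`, 0, "mean_mse")
    expect_true(all(diff(mses) >= 0))
  }
  expect_true(median(winners) <= 6)
  single <- select_hidden_size(3, "gdx", tiny_dataset(23),
                               cv_plan(k = 3, repeats = 1, seed = 1),
                               config = fast_train(seed = 1))
  expect_equal(single[[1]]$label, "3")
  expect_error(select_hidden_size(integer(0), "gdx", tiny_dataset(23)),
               "configuration error")
})

test_that("CV rankings serialize to the candidate/mean/repeat CSV layout", {
  data <- tiny_dataset(seed = 24, noise_sd = 0.3)
  res <- select_training_function(c("gdx", "lm"), data,
                                  cv_plan(k = 3, repeats = 2, seed = 2),
                                  hidden = 2, config = fast_train(seed = 1))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cv_csv(res, path)
  d <- read.csv(path)
  expect_equal(names(d), c("candidate", "mean_mse", "repeat_1", "repeat_2"))
  expect_equal(d$mean_mse, vapply(res, `[[`, 0, "mean_mse"), tolerance = 1e-6)
})
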