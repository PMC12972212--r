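test_that("metrics match hand-computed values and the brute-force oracle", {
  m <- compute_metrics(c(10, 20), c(12, 18))
  expect_equal(m$mae, 2)
  expect_equal(m$rmse, 2)
  expect_equal(m$mbe, 0)
  ident <- compute_metrics(c(3, 9, 40), c(3, 9, 40))
  expect_equal(ident$mae, 0)
  expect_equal(ident$rmse, 0)
  expect_equal(ident$r_squared, 1)
  m3 <- compute_metrics(c(1, 2, 4), c(1, 2, 3))
  expect_equal(m3$mae, 1 / 3, tolerance = 1e-12)
  expect_equal(m3$rmse, 1 / sqrt(3), tolerance = 1e-12)
  expect_equal(m3$mbe, 1 / 3, tolerance = 1e-12)
  set.seed(51)
  for (i in 1:10) {
    p <- runif(37, 0, 100)
    r <- runif(37, 0, 100)
    got <- compute_metrics(p, r)
    want <- oracle_metrics(p, r)
    expect_equal(got$mae, want$mae, tolerance = 1e-12)
    expect_equal(got$rmse, want$rmse, tolerance = 1e-12)
    expect_equal(got$mbe, want$mbe, tolerance = 1e-12)
    expect_true(got$rmse >= got$mae)
    expect_true(abs(got$mbe) <= got$mae)
  }
  expect_error(compute_metrics(numeric(0), numeric(0)), "empty")
  expect_true(is.na(compute_metrics(c(1, 2), c(5, 5))$r_squared))
})

test_that("fold assignment is balanced, exhaustive and seed-deterministic", {
  f <- make_folds(100, 10, seed = 1)
  expect_equal(as.vector(table(f$fold)), rep(10L, 10))
  f2 <- make_folds(101, 10, seed = 1)
  expect_equal(sort(as.vector(table(f2$fold))), c(rep(10L, 9), 11L))
  expect_identical(make_folds(57, 5, seed = 9)$fold,
                   make_folds(57, 5, seed = 9)$fold)
  expect_false(identical(make_folds(57, 5, seed = 9)$fold,
                         make_folds(57, 5, seed = 10)$fold))
  expect_error(make_folds(5, 10), "exceeds")
  expect_error(make_folds(100, 1), "at least 2")
})

test_that("cross-validation gives every sample one out-of-fold prediction", {
  sim <- simulate_dataset(sim_config(n_samples = 300, n_sites = 25,
                                     n_informative = 12, seed = 52))
  rep_ <- run_cross_validation(sim$dataset, k = 3, seed = 2, cutoff = 25)
  expect_equal(nrow(rep_$predictions), 300)
  expect_false(anyNA(rep_$predictions$final_age))
  expect_equal(sort(unique(rep_$predictions$fold)), 1:3)
  # deterministic given seed: same call, same report
  rep2 <- run_cross_validation(sim$dataset, k = 3, seed = 2, cutoff = 25)
  expect_identical(rep_$predictions, rep2$predictions)
})

test_that("noise-free linear data cross-validates to near-exact recovery", {
  sim <- simulate_dataset(sim_config(n_samples = 400, n_sites = 20,
                                     n_informative = 16, noise_scale = 0,
                                     curve_family = "linear", seed = 53))
  rep_ <- run_cross_validation(sim$dataset, k = 4, seed = 3, cutoff = 25)
  expect_lte(rep_$metrics$overall$mae, 1)
})

test_that("penalized baselines behave at the shrinkage extremes", {
  sim <- simulate_dataset(sim_config(n_samples = 300, n_sites = 25,
                                     n_informative = 16, noise_scale = 0,
                                     curve_family = "linear", seed = 54))
  # near-unpenalized LASSO on noise-free linear data: ~zero training error
  fit <- fit_penalized_baseline(sim$dataset, lambda = 1e-6, l1_ratio = 1)
  pred <- predict(fit, sim$dataset)
  expect_lte(mean(abs(pred - sim$dataset$ages)), 0.5)
  # heavy shrinkage: all coefficients zero, prediction = mean training age
  heavy <- fit_penalized_baseline(sim$dataset, lambda = 1e4, l1_ratio = 1)
  ph <- predict(heavy, sim$dataset)
  expect_equal(unname(ph), rep(mean(sim$dataset$ages), 300),
               tolerance = 1e-6)
})

test_that("the baseline rejects an all-constant design", {
  m <- matrix(0.5, 40, 3,
              dimnames = list(sprintf("s%d", 1:40), sprintf("cg%d", 1:3)))
  ds <- methylation_dataset(m, ages = sample(0:99, 40))
  expect_error(fit_penalized_baseline(ds), "degenerate design")
})

test_that("residual diagnostics recover known bias patterns", {
  real <- seq(0, 100, length.out = 60)
  offset <- residual_diagnostics(real + 5, real)
  expect_equal(offset$slope, 0, tolerance = 1e-10)
  expect_equal(offset$mean_residual, 5)
  shrunk <- residual_diagnostics(0.5 * real, real)
  expect_equal(shrunk$slope, -0.5, tolerance = 1e-10)
  expect_lt(shrunk$correlation, -0.99)
  expect_error(residual_diagnostics(1:5, 1:5), "at least 10")
})

test_that("the clock is less age-biased than a LASSO baseline on curved data", {
  # saturating trends (nonlinear junior regime): a linear model's residuals
  # correlate strongly with age, the grid-MLE clock's much less
  sim <- simulate_dataset(sim_config(
    n_samples = 900, n_sites = 40, n_informative = 16,
    curve_family = "logarithmic", seed = 55))
  tr <- subset(sim$dataset, samples = 1:700)
  te <- subset(sim$dataset, samples = 701:900)
  model <- suppressWarnings(train_two_stage(tr, cutoff = 25))
  clock_pred <- predict_two_stage(model, te)$final_age
  lasso <- fit_penalized_baseline(tr, lambda = 0.01, l1_ratio = 1)
  lasso_pred <- predict(lasso, te)
  d_clock <- residual_diagnostics(clock_pred, te$ages)
  d_lasso <- residual_diagnostics(lasso_pred, te$ages)
  expect_lt(abs(d_clock$correlation), abs(d_lasso$correlation))
})
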