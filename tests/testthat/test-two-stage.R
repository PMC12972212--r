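test_that("stage-1 training picks the informative sites at low noise", {
  sim <- simulate_dataset(sim_config(n_samples = 400, n_sites = 100,
                                     n_informative = 16,
                                     noise_scale = 0.01, seed = 41))
  ref <- train_stage1(sim$dataset)
  inf <- sim$truth$sites$site_id[sim$truth$sites$informative]
  expect_setequal(ref$site_ids, inf)
  # the screened universe is recorded and contains everything selected
  expect_true(all(ref$site_ids %in% attr(ref, "screened_sites")))
})

test_that("training is invariant to sample order", {
  sim <- simulate_dataset(sim_config(n_samples = 200, n_sites = 30,
                                     n_informative = 10, seed = 42))
  perm <- sample(length(sim$dataset$sample_ids))
  shuffled <- subset(sim$dataset, samples = perm)
  r1 <- train_stage1(sim$dataset)
  r2 <- train_stage1(shuffled)
  expect_identical(r1$site_ids, r2$site_ids)
  expect_equal(r1$mu, r2$mu, tolerance = 1e-12)
  expect_equal(r1$sigma, r2$sigma, tolerance = 1e-12)
})

test_that("identical ages make LOWESS training fail loudly", {
  m <- matrix(runif(60, 0.2, 0.8), 20, 3,
              dimnames = list(sprintf("s%d", 1:20), sprintf("cg%d", 1:3)))
  ds <- methylation_dataset(m, ages = rep(50, 20))
  # constant ages: correlations are undefined, so no site survives
  expect_error(suppressWarnings(train_stage1(ds, clock_config(n_sites = 2))),
               "too few usable sites|degenerate")
})

test_that("cohort models are trained independently per age cohort", {
  sim <- simulate_dataset(sim_config(
    n_samples = 800, n_sites = 40, n_informative = 16,
    curve_family = "piecewise", changepoint_age = 25, seed = 43))
  cohorts <- train_cohort_models(sim$dataset, 25)
  expect_s3_class(cohorts$junior, "reference_matrix")
  expect_s3_class(cohorts$senior, "reference_matrix")
  # piecewise truth: junior trend much steeper than senior trend, and the
  # cohort references reflect that over their own age ranges
  jr_slope <- rowMeans(cohorts$junior$mu[, as.character(21:25)]) -
    rowMeans(cohorts$junior$mu[, as.character(1:5)])
  inf <- sim$truth$sites
  amp <- inf$amplitude[match(cohorts$junior$site_ids, inf$site_id)]
  expect_true(all(sign(jr_slope) == sign(amp)))
})

test_that("an empty cohort is a hard error naming the cohort", {
  sim <- simulate_dataset(sim_config(n_samples = 100, n_sites = 20,
                                     n_informative = 8, age_min = 40,
                                     age_max = 90, seed = 44))
  expect_error(train_cohort_models(sim$dataset, 25), "junior cohort")
  expect_error(train_cohort_models(sim$dataset, 95), "senior cohort")
})

test_that("routing obeys the inclusive junior boundary", {
  sim <- simulate_dataset(sim_config(n_samples = 500, n_sites = 30,
                                     n_informative = 12, seed = 45))
  model <- train_two_stage(sim$dataset, cutoff = 25)
  pred <- predict_two_stage(model, sim$dataset)
  expect_true(all(pred$cohort[pred$stage1_age <= 25] == "junior"))
  expect_true(all(pred$cohort[pred$stage1_age >= 26] == "senior"))
  # partition: every predicted sample routed to exactly one cohort
  expect_true(all(pred$cohort %in% c("junior", "senior")))
})

test_that("degenerate two-stage model reproduces stage-1 predictions", {
  sim <- simulate_dataset(sim_config(n_samples = 200, n_sites = 30,
                                     n_informative = 12, seed = 46))
  ref <- train_stage1(sim$dataset)
  model <- betaclock:::new_two_stage_model(ref, ref, ref, 25,
                                           clock_config())
  pred <- predict_two_stage(model, sim$dataset)
  expect_equal(pred$final_age, pred$stage1_age)
})

test_that("noise-free piecewise juniors are recovered by the junior model", {
  cfg <- sim_config(n_samples = 900, n_sites = 24, n_informative = 16,
                    noise_scale = 0, curve_family = "piecewise",
                    changepoint_age = 25, seed = 47)
  sim <- simulate_dataset(cfg)
  model <- train_two_stage(sim$dataset, cutoff = 25)
  te <- which(sim$dataset$ages <= 20)
  pred <- predict_two_stage(model, subset(sim$dataset, samples = te))
  err <- abs(pred$final_age - sim$dataset$ages[te])
  # piecewise-linear segments are reproduced exactly by local-linear fits
  # away from the changepoint, so junior recovery is essentially exact
  expect_lte(median(err), 1)
})

test_that("cutoff scan selects the least-biased candidate with ties to the smallest", {
  sim <- simulate_dataset(sim_config(
    n_samples = 1100, n_sites = 40, n_informative = 16,
    curve_family = "piecewise", changepoint_age = 20, seed = 48))
  tr <- subset(sim$dataset, samples = 1:900)
  va <- subset(sim$dataset, samples = 901:1100)
  scan <- optimize_cutoff(tr, va, candidates = 16:24)
  expect_true(scan$selected %in% 16:24)
  expect_equal(scan$selected,
               scan$scan$cutoff[order(abs(scan$scan$mbe),
                                      scan$scan$cutoff)][1])
  # single candidate: returned with its metrics
  one <- optimize_cutoff(tr, va, candidates = 25)
  expect_equal(one$selected, 25)
  expect_equal(nrow(one$scan), 1)
})

test_that("sex-specific training runs the full pipeline per sex", {
  sim <- simulate_dataset(sim_config(n_samples = 600, n_sites = 30,
                                     n_informative = 12,
                                     sex_effect_size = 0, seed = 49))
  models <- train_sex_specific(sim$dataset, cutoff = 25)
  expect_equal(models$male$sex_label, "male")
  expect_equal(models$female$sex_label, "female")
  inf <- sim$truth$sites$site_id[sim$truth$sites$informative]
  # with no sex effect both models draw their sites from the informative set
  expect_true(all(models$male$stage1$site_ids %in% inf))
  expect_true(all(models$female$stage1$site_ids %in% inf))
})

test_that("sex-specific training rejects unusable sex data", {
  sim <- simulate_dataset(sim_config(n_samples = 100, n_sites = 20,
                                     n_informative = 8, seed = 50))
  ds <- sim$dataset
  ds$sex <- rep("unknown", length(ds$sex))
  expect_error(suppressWarnings(train_sex_specific(ds, cutoff = 25)),
               "sex group")
})
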