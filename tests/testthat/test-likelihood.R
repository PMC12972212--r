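test_that("beta shape parameters invert the Beta moment identities", {
  s <- beta_shape_params(0.5, 0.05)
  expect_equal(s$alpha, 2, tolerance = 1e-12)
  expect_equal(s$beta, 2, tolerance = 1e-12)
  s2 <- beta_shape_params(0.2, 0.01)
  expect_equal(s2$alpha, 3, tolerance = 1e-12)
  expect_equal(s2$beta, 12, tolerance = 1e-12)
  # round trip through the moment identities for random feasible pairs
  set.seed(20)
  mu <- runif(1000, 0.01, 0.99)
  v <- runif(1000, 0, 1) * mu * (1 - mu) * 0.98 + 1e-8
  sh <- beta_shape_params(mu, v)
  expect_true(all(sh$alpha > 0 & sh$beta > 0))
  mean_back <- sh$alpha / (sh$alpha + sh$beta)
  var_back <- sh$alpha * sh$beta /
    ((sh$alpha + sh$beta)^2 * (sh$alpha + sh$beta + 1))
  expect_equal(mean_back, mu, tolerance = 1e-10)
  expect_equal(var_back, v, tolerance = 1e-10)
})

test_that("infeasible moments and domain violations are rejected", {
  expect_error(beta_shape_params(0.5, 0.25), "infeasible")
  expect_error(beta_shape_params(0.5, 0.3), "infeasible")
  expect_error(beta_shape_params(0, 0.01), "mu")
  expect_error(beta_shape_params(1, 0.01), "mu")
  expect_error(beta_shape_params(0.5, 0), "var")
})

test_that("beta log-density matches closed forms and dbeta", {
  expect_equal(log_prob_beta(0.37, 1, 1), 0)           # uniform
  expect_equal(log_prob_beta(0.5, 2, 1), 0)            # density 2x at 1/2
  expect_equal(log_prob_beta(0.5, 2, 2), log(1.5), tolerance = 1e-12)
  set.seed(21)
  x <- runif(200, 0.01, 0.99)
  a <- runif(200, 0.2, 50)
  b <- runif(200, 0.2, 50)
  expect_equal(log_prob_beta(x, a, b), dbeta(x, a, b, log = TRUE),
               tolerance = 1e-10)
  expect_error(log_prob_beta(NaN, 2, 2), "non-finite")
})

test_that("normal log-density matches the closed form", {
  expect_equal(log_prob_normal(0.3, 0.3, 1), -0.5 * log(2 * pi),
               tolerance = 1e-12)
  expect_equal(log_prob_normal(1.3, 0.3, 1), -0.5 * log(2 * pi) - 0.5,
               tolerance = 1e-12)
  expect_equal(log_prob_normal(0.3, 0.3, 0.5),
               -0.5 * log(2 * pi) + log(2), tolerance = 1e-12)
  set.seed(22)
  x <- runif(100)
  mu <- runif(100)
  sg <- runif(100, 0.01, 0.2)
  expect_equal(log_prob_normal(x, mu, sg),
               -0.5 * log(2 * pi) - log(sg) - (x - mu)^2 / (2 * sg^2),
               tolerance = 1e-10)
  expect_error(log_prob_normal(0.5, 0.5, 0), "sigma")
})

make_toy_reference <- function(sites, grid = 0:100,
                               mu_fun = function(a, j) {
                                 0.2 + 0.006 * a + 0.02 * j
                               },
                               sigma = 0.05) {
  mu <- t(sapply(seq_along(sites), function(j) mu_fun(grid, j)))
  sg <- matrix(sigma, length(sites), length(grid))
  dimnames(mu) <- dimnames(sg) <- list(sites, as.character(grid))
  structure(list(site_ids = sites, age_grid = grid, mu = mu, sigma = sg),
            class = "reference_matrix")
}

test_that("a Gaussian profile peaks exactly at the matching grid age", {
  ref <- make_toy_reference("cgA")
  a_star <- 42
  x <- c(cgA = unname(ref$mu["cgA", as.character(a_star)]))
  prof <- age_log_likelihood(x, ref, family = "normal")
  expect_equal(predict_age(prof), a_star)
})

test_that("sites missing in the sample are silently excluded", {
  ref <- make_toy_reference(c("cgA", "cgB"))
  x_full <- c(cgA = 0.4, cgB = NA)
  prof <- age_log_likelihood(x_full, ref)
  prof_one <- age_log_likelihood(c(cgA = 0.4),
                                 make_toy_reference("cgA"))
  expect_equal(prof$log_likelihood, prof_one$log_likelihood)
  expect_equal(prof$n_sites_used, 1)
  expect_error(age_log_likelihood(c(cgZ = 0.4), ref), "no overlap")
})

test_that("the profile equals a naive per-site loop-and-sum oracle", {
  set.seed(23)
  sites <- sprintf("cg%02d", 1:16)
  ref <- make_toy_reference(sites,
                            mu_fun = function(a, j) {
                              pmin(0.1 + 0.004 * a + 0.03 * j, 0.95)
                            })
  ref$sigma[] <- runif(length(ref$sigma), 0.02, 0.1)
  x <- setNames(runif(16, 0.05, 0.95), sites)
  for (family in c("normal", "beta")) {
    prof <- age_log_likelihood(x, ref, family = family)
    oracle <- sapply(seq_along(ref$age_grid), function(ai) {
      sum(sapply(sites, function(s) {
        mu <- ref$mu[s, ai]
        sg <- ref$sigma[s, ai]
        if (family == "normal") {
          dnorm(x[s], mu, sg, log = TRUE)
        } else {
          v <- min(sg^2, 0.99 * mu * (1 - mu))
          nu <- mu * (1 - mu) / v - 1
          dbeta(x[s], mu * nu, (1 - mu) * nu, log = TRUE)
        }
      }))
    })
    expect_equal(prof$log_likelihood, oracle, tolerance = 1e-10)
  }
})

test_that("argmax ties break toward the youngest age", {
  prof <- structure(
    list(age_grid = 0:100,
         log_likelihood = rep(c(-5, -1), length.out = 101),
         n_sites_used = 1),
    class = "age_likelihood_profile")
  expect_equal(predict_age(prof), 1)
  prof$log_likelihood <- rep(-2, 101)
  prof$log_likelihood[c(31, 41)] <- -1  # ages 30 and 40 tie
  expect_equal(predict_age(prof), 30)
})

test_that("a flat-reference site shifts the profile but not the argmax", {
  ref <- make_toy_reference(c("cgA", "cgB"),
                            mu_fun = function(a, j) {
                              if (j == 1) 0.22 + 0.006 * a
                              else rep(0.5, length(a))
                            })
  x <- c(cgA = 0.38, cgB = 0.44)
  with_flat <- age_log_likelihood(x, ref)
  without <- age_log_likelihood(c(cgA = 0.38), make_toy_reference("cgA"))
  expect_equal(predict_age(with_flat), predict_age(without))
  # the flat site adds the same constant at every age
  shift <- with_flat$log_likelihood - without$log_likelihood
  expect_equal(max(shift) - min(shift), 0, tolerance = 1e-12)
})

test_that("the normalized posterior sums to one", {
  ref <- make_toy_reference("cgA")
  prof <- age_log_likelihood(c(cgA = 0.5), ref)
  post <- posterior_age_distribution(prof)
  expect_equal(sum(post), 1, tolerance = 1e-12)
  expect_true(all(post >= 0))
  expect_equal(ref$age_grid[which.max(post)], predict_age(prof))
})

test_that("beta-family evaluation stays finite at boundary beta values", {
  ref <- make_toy_reference("cgA")
  for (xv in c(0, 1)) {
    prof <- age_log_likelihood(c(cgA = xv), ref, family = "beta")
    expect_true(all(is.finite(prof$log_likelihood)))
  }
})

test_that("predictions always land inside the age grid", {
  set.seed(24)
  ref <- make_toy_reference(c("cgA", "cgB"))
  for (i in 1:25) {
    x <- setNames(runif(2), c("cgA", "cgB"))
    prof <- age_log_likelihood(x, ref)
    a <- predict_age(prof)
    expect_gte(a, 0)
    expect_lte(a, 100)
  }
})
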