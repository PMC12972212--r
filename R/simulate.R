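#' Synthetic methylation data: simulation configuration
#'
#' Describes a synthetic cohort with the statistical structure the clock
#' assumes: a subset of "informative" CpG sites whose mean methylation follows
#' a monotone trend with age (saturating logarithmic by default, since
#' methylation changes more rapidly at younger ages), the remainder flat
#' noise, with optional methylation-level-dependent (heteroscedastic) noise
#' variance, sex offsets and missingness.
#'
#' Informative trends are `mu_j(a) = b_j + s_j * g(a)` with `g` one of
#' * `"logarithmic"`: `g(a) = log(1 + a) / log(1 + age_max)`;
#' * `"linear"`: `g(a) = a / age_max`;
#' * `"piecewise"`: linear with a steeper slope below `changepoint_age` and a
#'   shallower slope above it (slope ratio `piecewise_ratio`), normalized so
#'   `g(age_max) = 1`.
#'
#' Gaussian noise has standard deviation `noise_scale * sqrt(1 + 4*mu*(1-mu))`
#' when `heteroscedastic = TRUE` (variance largest at intermediate
#' methylation, as on arrays) and `noise_scale` otherwise; values are clipped
#' to \[0, 1\] afterwards. `noise_family = "beta"` instead draws from a Beta
#' distribution moment-matched to the same mean and variance.
#'
#' @param n_samples Number of samples.
#' @param n_sites Total number of CpG sites.
#' @param n_informative Number of age-informative sites (`<= n_sites`).
#' @param age_min,age_max Age range; ages are drawn uniformly on the integers
#'   `age_min..age_max` (the reference grid is in whole years).
#' @param noise_scale Base standard deviation of beta-value noise.
#' @param heteroscedastic If `TRUE`, noise variance depends on the mean level
#'   as `v(mu) = noise_scale^2 * (1 + 4*mu*(1-mu))`.
#' @param curve_family Trend family for informative sites (one of
#'   `"logarithmic"`, `"linear"`, `"piecewise"`, or a vector of length
#'   `n_informative` mixing them).
#' @param changepoint_age Kink age for piecewise trends.
#' @param piecewise_ratio Junior/senior slope ratio for piecewise trends
#'   (> 1 means faster change before the changepoint).
#' @param amplitude_range Range of absolute trend amplitudes `|s_j|`; each
#'   informative site gets a random sign.
#' @param sex_effect_size Additive beta-value offset applied, for male
#'   samples, to a random 25% of informative sites (at least one) when > 0.
#' @param missing_rate Fraction of matrix entries masked as `NA`.
#' @param noise_family `"gaussian"` (truncated to \[0,1\]) or `"beta"`.
#' @param seed Integer seed; identical configs with the same seed produce
#'   bit-identical datasets.
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_samples = 500L,
                       n_sites = 100L,
                       n_informative = 16L,
                       age_min = 0L,
                       age_max = 100L,
                       noise_scale = 0.03,
                       heteroscedastic = TRUE,
                       curve_family = "logarithmic",
                       changepoint_age = 20L,
                       piecewise_ratio = 4,
                       amplitude_range = c(0.25, 0.6),
                       sex_effect_size = 0,
                       missing_rate = 0,
                       noise_family = c("gaussian", "beta"),
                       seed = 1L) {
  noise_family <- match.arg(noise_family)
  if (n_informative > n_sites) {
    stop("invalid config: n_informative (", n_informative,
         ") exceeds n_sites (", n_sites, ")", call. = FALSE)
  }
  if (age_min > age_max) {
    stop("invalid config: age_min > age_max", call. = FALSE)
  }
  fam <- as.character(curve_family)
  if (!length(fam) %in% c(1L, max(1L, n_informative))) {
    stop("curve_family must have length 1 or n_informative", call. = FALSE)
  }
  if (any(fam == "piecewise") &&
      (changepoint_age <= age_min || changepoint_age >= age_max)) {
    stop("invalid config: changepoint_age must lie strictly inside ",
         "[age_min, age_max]", call. = FALSE)
  }
  if (!all(fam %in% c("logarithmic", "linear", "piecewise"))) {
    stop("unknown curve_family: ",
         paste(setdiff(fam, c("logarithmic", "linear", "piecewise")),
               collapse = ", "), call. = FALSE)
  }
  stopifnot(
    n_samples >= 1, n_sites >= 1, n_informative >= 0,
    noise_scale >= 0, missing_rate >= 0, missing_rate < 1,
    piecewise_ratio > 0,
    length(amplitude_range) == 2L, amplitude_range[1] > 0,
    amplitude_range[2] <= 1, amplitude_range[1] <= amplitude_range[2],
    sex_effect_size >= 0, sex_effect_size < 1
  )
  structure(
    list(n_samples = as.integer(n_samples), n_sites = as.integer(n_sites),
         n_informative = as.integer(n_informative),
         age_min = as.integer(age_min), age_max = as.integer(age_max),
         noise_scale = as.numeric(noise_scale),
         heteroscedastic = isTRUE(heteroscedastic),
         curve_family = fam,
         changepoint_age = as.numeric(changepoint_age),
         piecewise_ratio = as.numeric(piecewise_ratio),
         amplitude_range = as.numeric(amplitude_range),
         sex_effect_size = as.numeric(sex_effect_size),
         missing_rate = as.numeric(missing_rate),
         noise_family = noise_family,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

## Normalized trend shape g(a) in [0, 1]; vectorized over `age`.
curve_shape <- function(age, family, age_max, changepoint, ratio) {
  switch(family,
    logarithmic = log1p(age) / log1p(age_max),
    linear = age / age_max,
    piecewise = {
      g <- ratio * pmin(age, changepoint) + pmax(age - changepoint, 0)
      g / (ratio * changepoint + (age_max - changepoint))
    },
    stop("unknown curve family: ", family, call. = FALSE)
  )
}

#' Simulate a synthetic methylation dataset
#'
#' Generates a beta-value matrix (with per-sample ages and sex) and the
#' ground truth needed to evaluate recovery: every site's trend family,
#' baseline and amplitude, and each sample's true age.
#'
#' @param config A [sim_config()].
#' @return A list with elements `dataset` (a [methylation_dataset()]) and
#'   `truth` (class `ground_truth`: a per-site parameter table plus the true
#'   ages, queryable through [true_mean()]).
#' @export
#' @examples
#' sim <- simulate_dataset(sim_config(n_samples = 50, n_sites = 20, seed = 7))
#' sim$dataset
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_samples
  p <- config$n_sites
  J <- config$n_informative

  ages <- sample(seq(config$age_min, config$age_max), n, replace = TRUE)
  sex <- sample(c("female", "male"), n, replace = TRUE)

  family <- rep("flat", p)
  if (J > 0) {
    family[seq_len(J)] <- rep(config$curve_family, length.out = J)
  }
  amplitude <- numeric(p)
  baseline <- runif(p, 0.05, 0.95)
  if (J > 0) {
    mag <- runif(J, config$amplitude_range[1], config$amplitude_range[2])
    sign <- sample(c(-1, 1), J, replace = TRUE)
    amplitude[seq_len(J)] <- mag * sign
    # keep the full trend inside [0.05, 0.95] so boundary clipping stays rare
    up <- seq_len(J)[sign > 0]
    dn <- seq_len(J)[sign < 0]
    baseline[up] <- runif(length(up), 0.05, 0.95 - mag[sign > 0])
    baseline[dn] <- runif(length(dn), 0.05 + mag[sign < 0], 0.95)
  }
  site_ids <- sprintf("cg%08d", seq_len(p))
  sample_ids <- sprintf("sample_%04d", seq_len(n))

  sex_sites <- character(0)
  if (config$sex_effect_size > 0 && J > 0) {
    n_aff <- max(1L, round(0.25 * J))
    sex_sites <- site_ids[sample(seq_len(J), n_aff)]
  }

  truth <- structure(
    list(
      sites = data.frame(
        site_id = site_ids, family = family, baseline = baseline,
        amplitude = amplitude, informative = seq_len(p) <= J,
        sex_affected = site_ids %in% sex_sites,
        stringsAsFactors = FALSE
      ),
      ages = setNames(ages, sample_ids),
      sex = setNames(sex, sample_ids),
      age_min = config$age_min, age_max = config$age_max,
      changepoint_age = config$changepoint_age,
      piecewise_ratio = config$piecewise_ratio,
      sex_effect_size = config$sex_effect_size,
      affected_sex = "male"
    ),
    class = "ground_truth"
  )

  mu <- vapply(seq_len(p), function(j) {
    true_mean_impl(truth, j, ages)
  }, numeric(n))
  if (length(sex_sites) > 0) {
    male <- sex == "male"
    jj <- match(sex_sites, site_ids)
    mu[male, jj] <- pmin(pmax(mu[male, jj] + config$sex_effect_size, 0), 1)
  }

  if (config$noise_scale > 0) {
    v <- if (config$heteroscedastic) {
      config$noise_scale^2 * (1 + 4 * mu * (1 - mu))
    } else {
      matrix(config$noise_scale^2, n, p)
    }
    if (config$noise_family == "gaussian") {
      x <- mu + rnorm(n * p, 0, sqrt(v))
    } else {
      # Beta noise moment-matched to (mu, v); variance capped below the
      # Bernoulli bound so the shape parameters stay positive.
      muc <- pmin(pmax(mu, 1e-3), 1 - 1e-3)
      vc <- pmin(v, 0.99 * muc * (1 - muc))
      nu <- muc * (1 - muc) / vc - 1
      x <- rbeta(n * p, muc * nu, (1 - muc) * nu)
    }
    x <- matrix(x, n, p)
  } else {
    x <- mu
  }
  x <- pmin(pmax(x, 0), 1)

  if (config$missing_rate > 0) {
    x[runif(n * p) < config$missing_rate] <- NA_real_
  }
  dimnames(x) <- list(sample_ids, site_ids)

  list(
    dataset = methylation_dataset(x, ages = ages, sex = sex),
    truth = truth
  )
}

true_mean_impl <- function(truth, j, age) {
  row <- truth$sites[j, ]
  if (row$family == "flat") {
    return(rep(row$baseline, length(age)))
  }
  g <- curve_shape(age, row$family, truth$age_max,
                   truth$changepoint_age, truth$piecewise_ratio)
  pmin(pmax(row$baseline + row$amplitude * g, 0), 1)
}

#' Noise-free trend value for a simulated site
#'
#' Oracle access to the generating curve: the expected (noise-free, clipped)
#' methylation level of `site` at `age`, before any sex offset.
#'
#' @param truth A `ground_truth` object from [simulate_dataset()].
#' @param site A site id present in the simulation.
#' @param age Age(s) in years within the simulated range.
#' @return Methylation level(s) in \[0, 1\].
#' @export
#' @examples
#' sim <- simulate_dataset(sim_config(n_samples = 10, n_sites = 5, seed = 1))
#' true_mean(sim$truth, sim$truth$sites$site_id[1], c(0, 50, 100))
true_mean <- function(truth, site, age) {
  stopifnot(inherits(truth, "ground_truth"))
  j <- match(site, truth$sites$site_id)
  if (is.na(j)) stop("unknown site: ", site, call. = FALSE)
  true_mean_impl(truth, j, age)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("Ground truth: %d sites (%d informative), %d samples\n",
              nrow(x$sites), sum(x$sites$informative), length(x$ages)))
  fams <- table(x$sites$family[x$sites$informative])
  if (length(fams)) {
    cat("  informative families: ",
        paste(sprintf("%s=%d", names(fams), fams), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "Simulation config: %d samples, %d sites (%d informative, %s), ages %d..%d\n",
    x$n_samples, x$n_sites, x$n_informative,
    paste(unique(x$curve_family), collapse = "/"), x$age_min, x$age_max))
  cat(sprintf("  noise %g (%s, %s), missing %g, sex effect %g, seed %d\n",
              x$noise_scale, x$noise_family,
              if (x$heteroscedastic) "heteroscedastic" else "constant",
              x$missing_rate, x$sex_effect_size, x$seed))
  invisible(x)
}
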