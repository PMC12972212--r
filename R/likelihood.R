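#' Beta-distribution shape parameters from mean and variance
#'
#' Method-of-moments inversion used by the beta likelihood family:
#' `alpha = mu * (-mu^2 + mu - var) / var` and
#' `beta = (mu - 1) * (mu^2 - mu + var) / var`, the unique shape pair with
#' mean `alpha / (alpha + beta) = mu` and variance
#' `alpha * beta / ((alpha + beta)^2 (alpha + beta + 1)) = var`.
#'
#' Feasibility requires `0 < var < mu * (1 - mu)` (the Bernoulli bound);
#' callers clip variances before invoking this.
#'
#' @param mu Mean methylation level(s) in (0, 1). Vectorized.
#' @param var Variance(s), `0 < var < mu * (1 - mu)`.
#' @return A list with numeric components `alpha` and `beta`, both > 0.
#' @export
#' @examples
#' beta_shape_params(0.5, 0.05)  # alpha = beta = 2
beta_shape_params <- function(mu, var) {
  if (any(!is.finite(mu)) || any(mu <= 0) || any(mu >= 1)) {
    stop("mu must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (any(!is.finite(var)) || any(var <= 0)) {
    stop("var must be strictly positive", call. = FALSE)
  }
  if (any(var >= mu * (1 - mu))) {
    stop("infeasible moments: var must be below mu * (1 - mu)",
         call. = FALSE)
  }
  alpha <- mu * (-mu^2 + mu - var) / var
  beta <- (mu - 1) * (mu^2 - mu + var) / var
  list(alpha = alpha, beta = beta)
}

#' Log-density of a beta value under a Beta distribution
#'
#' Evaluated through log-gamma (never the raw gamma function, which would
#' overflow for the large shape parameters that small variances produce).
#'
#' @param x Observed methylation level(s); callers clip into
#'   `[x_eps, 1 - x_eps]` beforehand.
#' @param alpha,beta Shape parameters (> 0). Vectorized/recycled.
#' @return Log-density values.
#' @export
log_prob_beta <- function(x, alpha, beta) {
  if (any(!is.finite(x))) stop("non-finite methylation value", call. = FALSE)
  lgamma(alpha + beta) - lgamma(alpha) - lgamma(beta) +
    (alpha - 1) * log(x) + (beta - 1) * log1p(-x)
}

#' Log-density of a beta value under a normal distribution
#'
#' @param x Observed methylation level(s).
#' @param mu Expected methylation level at the candidate age.
#' @param sigma Standard deviation (> 0, floored upstream).
#' @return Log-density values.
#' @export
log_prob_normal <- function(x, mu, sigma) {
  if (any(sigma <= 0)) stop("sigma must be positive", call. = FALSE)
  dnorm(x, mean = mu, sd = sigma, log = TRUE)
}

#' Age log-likelihood profile for one sample
#'
#' Scores a sample's observed beta values against a reference matrix at every
#' candidate age: `L(a)` is the sum over available sites of the log-density
#' of the observed value under the reference `(mu_j(a), sigma_j(a))`.
#' Reference sites that are missing (or `NA`) in the sample are silently
#' excluded — intersection semantics, which is what makes the clock robust to
#' missing probes — and `n_sites_used` records how many entered the sum.
#'
#' For the beta family, per-(site, age) variances that violate the Bernoulli
#' feasibility bound are clipped to `feasibility_fraction * mu * (1 - mu)`
#' before the shape parameters are computed, and both the reference means and
#' the observation are clipped `x_eps` away from 0/1.
#'
#' @param sample_betas Named numeric vector of beta values (names = site
#'   ids), or a single row of a beta matrix.
#' @param reference A [build_reference_matrix()] result.
#' @param family `"normal"` or `"beta"`; defaults to the config's family.
#' @param config A [clock_config()].
#' @return An object of class `age_likelihood_profile` with fields
#'   `age_grid`, `log_likelihood`, `n_sites_used`.
#' @export
age_log_likelihood <- function(sample_betas, reference,
                               family = NULL, config = clock_config()) {
  stopifnot(inherits(reference, "reference_matrix"),
            inherits(config, "clock_config"))
  if (is.null(family)) family <- config$family
  family <- match.arg(family, c("normal", "beta"))
  x <- sample_betas
  if (is.null(names(x))) stop("sample_betas must be named by site id",
                              call. = FALSE)
  shared <- intersect(reference$site_ids, names(x)[!is.na(x)])
  if (length(shared) < config$min_sites) {
    stop("no overlap: sample shares ", length(shared),
         " non-missing sites with the reference (need >= ",
         config$min_sites, ")", call. = FALSE)
  }
  xs <- x[shared]
  mu <- reference$mu[shared, , drop = FALSE]
  sigma <- reference$sigma[shared, , drop = FALSE]
  if (family == "normal") {
    ll <- colSums(dnorm(xs, mean = mu, sd = sigma, log = TRUE))
  } else {
    eps <- config$x_eps
    muc <- pmin(pmax(mu, eps), 1 - eps)
    vc <- pmin(sigma^2, config$feasibility_fraction * muc * (1 - muc))
    shape <- beta_shape_params(muc, vc)
    xc <- pmin(pmax(xs, eps), 1 - eps)
    ll <- colSums(log_prob_beta(xc, shape$alpha, shape$beta))
  }
  structure(
    list(age_grid = reference$age_grid, log_likelihood = unname(ll),
         n_sites_used = length(shared)),
    class = "age_likelihood_profile"
  )
}

#' Maximum-likelihood age from a likelihood profile
#'
#' The grid age with maximal log-likelihood; exact ties are broken toward the
#' youngest age (deterministically).
#'
#' @param profile An [age_log_likelihood()] result.
#' @return Predicted age in years (an element of the grid).
#' @export
predict_age <- function(profile) {
  stopifnot(inherits(profile, "age_likelihood_profile"))
  profile$age_grid[which.max(profile$log_likelihood)]
}

#' Normalized posterior over the age grid
#'
#' `exp(L(a) - logsumexp(L))`: the likelihood profile normalized to sum to 1
#' across the grid (a flat prior over candidate ages is implied). Useful for
#' diagnostics and plotting; the point prediction is still the argmax.
#'
#' @param profile An [age_log_likelihood()] result.
#' @return Numeric vector of posterior masses over `profile$age_grid`.
#' @export
posterior_age_distribution <- function(profile) {
  stopifnot(inherits(profile, "age_likelihood_profile"))
  ll <- profile$log_likelihood
  m <- max(ll)
  w <- exp(ll - m)
  w / sum(w)
}

#' @export
print.age_likelihood_profile <- function(x, ...) {
  cat(sprintf(
    "Age likelihood profile over %d..%d (%d sites used); MLE age = %d\n",
    min(x$age_grid), max(x$age_grid), x$n_sites_used,
    x$age_grid[which.max(x$log_likelihood)]))
  invisible(x)
}

#' Predict ages for every sample in a dataset with one reference
#'
#' Convenience wrapper applying [age_log_likelihood()] + [predict_age()] per
#' sample. Samples with no usable site overlap get `NA` predictions with a
#' warning; the rest proceed.
#'
#' @param reference A `reference_matrix`.
#' @param dataset A [methylation_dataset()] (ages not required).
#' @param family,config As in [age_log_likelihood()].
#' @return A data.frame: `sample_id`, `age` (predicted), `n_sites_used`,
#'   `max_log_likelihood`.
#' @export
predict_ages <- function(reference, dataset, family = NULL,
                         config = clock_config()) {
  stopifnot(inherits(dataset, "methylation_dataset"))
  n <- length(dataset$sample_ids)
  age <- rep(NA_real_, n)
  nsu <- rep(NA_integer_, n)
  mll <- rep(NA_real_, n)
  failed <- character(0)
  for (i in seq_len(n)) {
    prof <- tryCatch(
      age_log_likelihood(dataset$beta[i, ], reference, family, config),
      error = function(e) NULL
    )
    if (is.null(prof)) {
      failed <- c(failed, dataset$sample_ids[i])
      next
    }
    age[i] <- predict_age(prof)
    nsu[i] <- prof$n_sites_used
    mll[i] <- max(prof$log_likelihood)
  }
  if (length(failed) > 0) {
    warning("no usable site overlap for sample(s): ",
            paste(failed, collapse = ", "), call. = FALSE)
  }
  data.frame(sample_id = dataset$sample_ids, age = age,
             n_sites_used = nsu, max_log_likelihood = mll,
             stringsAsFactors = FALSE)
}
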