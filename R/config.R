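#' Clock configuration
#'
#' Bundles every tunable of the training and prediction pipeline. Defaults
#' follow the published method: LOWESS smoothing fraction `tau = 0.7` (chosen
#' by the original authors from a 0.1-1.0 scan), `n_sites = 16` top
#' age-correlated CpG sites, Spearman screen at `min_abs_rho = 0.60`, and a
#' normal likelihood (the beta likelihood is available via `family = "beta"`).
#'
#' @param tau LOWESS smoothing fraction in (0, 1]: the fraction of points in
#'   each local regression window.
#' @param n_sites Number of top age-correlated CpG sites per reference matrix.
#' @param min_abs_rho Spearman screening threshold: sites with `|rho|` below
#'   this are dropped before selection.
#' @param family Likelihood family used to score an observed beta value
#'   against the reference, `"normal"` or `"beta"`.
#' @param sigma_floor Lower bound on the per-site, per-age standard deviation
#'   (beta-value units). Prevents degenerate spike likelihoods when an age
#'   bin's empirical variance is ~0.
#' @param min_bin_size Minimum number of same-age samples for an age bin to
#'   contribute a variance estimate.
#' @param n_robust_iters Robustifying iterations for the LOWESS fits
#'   (0 = plain tricube weights).
#' @param x_eps Clipping margin applied to observed beta values (and reference
#'   means) before beta-density evaluation, so log-densities stay finite at
#'   the 0/1 boundary.
#' @param feasibility_fraction When the beta family is used and a reference
#'   variance exceeds the Bernoulli bound `mu*(1-mu)`, it is clipped to this
#'   fraction of the bound before the shape parameters are computed.
#' @param min_cohort_size Minimum training samples per cohort in the two-stage
#'   split.
#' @param min_sites Minimum number of reference sites that must overlap a
#'   sample for a prediction to be attempted.
#' @param age_grid Integer candidate ages scored by the likelihood.
#'
#' @return An object of class `clock_config` (a validated list).
#' @export
#' @examples
#' clock_config(tau = 0.5, family = "beta")
clock_config <- function(tau = 0.7,
                         n_sites = 16L,
                         min_abs_rho = 0.60,
                         family = c("normal", "beta"),
                         sigma_floor = 0.01,
                         min_bin_size = 3L,
                         n_robust_iters = 0L,
                         x_eps = 1e-6,
                         feasibility_fraction = 0.99,
                         min_cohort_size = 30L,
                         min_sites = 1L,
                         age_grid = 0:100) {
  family <- match.arg(family)
  stopifnot(
    is.numeric(tau), length(tau) == 1L, tau > 0, tau <= 1,
    is.numeric(n_sites), length(n_sites) == 1L, n_sites >= 1,
    is.numeric(min_abs_rho), min_abs_rho >= 0, min_abs_rho <= 1,
    is.numeric(sigma_floor), sigma_floor > 0,
    is.numeric(min_bin_size), min_bin_size >= 2,
    is.numeric(n_robust_iters), n_robust_iters >= 0,
    is.numeric(x_eps), x_eps > 0, x_eps < 0.5,
    is.numeric(feasibility_fraction), feasibility_fraction > 0,
    feasibility_fraction < 1,
    is.numeric(min_cohort_size), min_cohort_size >= 2,
    is.numeric(min_sites), min_sites >= 1,
    is.numeric(age_grid), length(age_grid) >= 2, !is.unsorted(age_grid)
  )
  structure(
    list(
      tau = as.numeric(tau),
      n_sites = as.integer(n_sites),
      min_abs_rho = as.numeric(min_abs_rho),
      family = family,
      sigma_floor = as.numeric(sigma_floor),
      min_bin_size = as.integer(min_bin_size),
      n_robust_iters = as.integer(n_robust_iters),
      x_eps = as.numeric(x_eps),
      feasibility_fraction = as.numeric(feasibility_fraction),
      min_cohort_size = as.integer(min_cohort_size),
      min_sites = as.integer(min_sites),
      age_grid = as.integer(age_grid)
    ),
    class = "clock_config"
  )
}

#' @export
print.clock_config <- function(x, ...) {
  cat("Clock configuration\n")
  cat(sprintf("  tau = %g, n_sites = %d, min_abs_rho = %g, family = %s\n",
              x$tau, x$n_sites, x$min_abs_rho, x$family))
  cat(sprintf("  sigma_floor = %g, min_bin_size = %d, min_cohort_size = %d\n",
              x$sigma_floor, x$min_bin_size, x$min_cohort_size))
  cat(sprintf("  age grid: %d..%d\n", min(x$age_grid), max(x$age_grid)))
  invisible(x)
}
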