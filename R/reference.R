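#' Estimate a methylation-dependent variance curve for one site
#'
#' Treats samples of the same (integer) age as technical replicates: samples
#' are grouped into whole-year age bins, bins with at least `min_bin_size`
#' non-missing values contribute a `(mean methylation, unbiased variance,
#' size)` support point, and a LOWESS fit of variance against bin mean
#' methylation gives a smooth lookup from methylation level to variance.
#' Lookups interpolate between support points (sorted by bin mean) and are
#' constant-clamped outside their range; the returned variance is never below
#' `sigma_floor^2`.
#'
#' With fewer than two usable bins the curve degenerates, with a warning, to
#' the pooled variance of all non-missing values (a flat lookup).
#'
#' @param dataset A [methylation_dataset()] with ages.
#' @param site A site id.
#' @param config A [clock_config()] (uses `tau`, `min_bin_size`,
#'   `sigma_floor`, `n_robust_iters`).
#' @return An object of class `variance_curve` with fields `site_id`,
#'   `support` (data.frame `mu`, `var`, `n`) and a smoothed lookup; evaluate
#'   with [predict()].
#' @export
estimate_variance_curve <- function(dataset, site, config = clock_config()) {
  stopifnot(inherits(dataset, "methylation_dataset"),
            inherits(config, "clock_config"))
  j <- match(site, dataset$site_ids)
  if (is.na(j)) stop("unknown site: ", site, call. = FALSE)
  if (is.null(dataset$ages)) stop("dataset has no ages", call. = FALSE)
  x <- dataset$beta[, j]
  ok <- !is.na(x) & !is.na(dataset$ages)
  x <- x[ok]
  a <- round(dataset$ages[ok])
  bins <- split(x, a)
  bins <- bins[lengths(bins) >= config$min_bin_size]
  support <- data.frame(
    mu = vapply(bins, mean, numeric(1)),
    var = vapply(bins, var, numeric(1)),
    n = lengths(bins),
    row.names = NULL
  )
  if (nrow(support) < 2L) {
    warning("site ", site, ": fewer than 2 usable age bins; ",
            "falling back to a pooled variance", call. = FALSE)
    pooled <- if (length(x) >= 2) var(x) else config$sigma_floor^2
    fit <- NULL
  } else if (nrow(support) == 2L || length(unique(support$mu)) < 3L) {
    # too few distinct support abscissae to smooth: the lookup is the
    # (mu-averaged) line through the support points
    mu_u <- sort(unique(support$mu))
    var_u <- vapply(mu_u, function(m) mean(support$var[support$mu == m]),
                    numeric(1))
    if (length(mu_u) == 1L) {
      pooled <- var_u
      fit <- NULL
    } else {
      fit <- structure(list(x = mu_u, fitted = var_u, tau = config$tau,
                            n = nrow(support)), class = "lowess_fit")
      pooled <- NULL
    }
  } else {
    fit <- fit_lowess(support$mu, support$var, tau = config$tau,
                      n_robust_iters = config$n_robust_iters)
    pooled <- NULL
  }
  structure(
    list(site_id = site, support = support, fit = fit, pooled = pooled,
         sigma_floor = config$sigma_floor),
    class = "variance_curve"
  )
}

#' Evaluate a variance curve at methylation level(s)
#'
#' @param object A `variance_curve`.
#' @param mu Methylation level(s) in \[0, 1\].
#' @param ... Unused.
#' @return Variance estimates, floored at `sigma_floor^2`.
#' @export
predict.variance_curve <- function(object, mu, ...) {
  v <- if (is.null(object$fit)) {
    rep(object$pooled, length(mu))
  } else {
    predict(object$fit, mu)
  }
  pmax(v, object$sigma_floor^2)
}

#' @export
print.variance_curve <- function(x, ...) {
  cat(sprintf("Variance curve for %s: %d support bins%s\n", x$site_id,
              nrow(x$support),
              if (is.null(x$fit)) " (pooled fallback)" else ""))
  invisible(x)
}

#' Build a reference matrix of expected methylation and spread per age
#'
#' For each selected site, fits a LOWESS trend of methylation against age and
#' evaluates it at every grid age (0..100 by default), clipping to \[0, 1\];
#' grid ages outside the observed training age range take the boundary value
#' (constant extrapolation). The standard deviation at each grid age is read
#' off the site's variance-vs-methylation curve at the expected level:
#' `sigma(a) = sqrt(max(v(mu(a)), sigma_floor^2))`.
#'
#' @param dataset Training [methylation_dataset()] with ages.
#' @param sites Character vector of site ids to include.
#' @param config A [clock_config()].
#' @return An object of class `reference_matrix`: `site_ids`, `age_grid`,
#'   and `mu`, `sigma` matrices (sites x grid ages).
#' @export
#' @examples
#' sim <- simulate_dataset(sim_config(n_samples = 120, n_sites = 6,
#'                                    n_informative = 4, seed = 2))
#' ref <- build_reference_matrix(sim$dataset, sim$dataset$site_ids[1:4])
#' ref
build_reference_matrix <- function(dataset, sites, config = clock_config()) {
  stopifnot(inherits(dataset, "methylation_dataset"),
            inherits(config, "clock_config"))
  if (length(sites) == 0) stop("no sites given", call. = FALSE)
  if (is.null(dataset$ages)) stop("dataset has no ages", call. = FALSE)
  missing_sites <- setdiff(sites, dataset$site_ids)
  if (length(missing_sites) > 0) {
    stop("sites not in dataset: ", paste(missing_sites, collapse = ", "),
         call. = FALSE)
  }
  grid <- config$age_grid
  mu <- matrix(NA_real_, length(sites), length(grid),
               dimnames = list(sites, as.character(grid)))
  sigma <- mu
  kept <- logical(length(sites))
  for (i in seq_along(sites)) {
    s <- sites[i]
    x <- dataset$beta[, s]
    ok <- !is.na(x) & !is.na(dataset$ages)
    if (sum(ok) < 3L) {
      warning("site ", s, ": fewer than 3 usable values; excluded",
              call. = FALSE)
      next
    }
    trend <- fit_lowess(dataset$ages[ok], x[ok], tau = config$tau,
                        n_robust_iters = config$n_robust_iters)
    m <- pmin(pmax(predict(trend, grid), 0), 1)
    vcurve <- estimate_variance_curve(dataset, s, config)
    v <- predict(vcurve, m)
    mu[i, ] <- m
    sigma[i, ] <- sqrt(v)
    kept[i] <- TRUE
  }
  if (!any(kept)) stop("no usable sites for the reference matrix",
                       call. = FALSE)
  structure(
    list(site_ids = sites[kept], age_grid = grid,
         mu = mu[kept, , drop = FALSE], sigma = sigma[kept, , drop = FALSE]),
    class = "reference_matrix"
  )
}

#' @export
print.reference_matrix <- function(x, ...) {
  cat(sprintf("Reference matrix: %d sites x %d grid ages (%d..%d)\n",
              length(x$site_ids), length(x$age_grid), min(x$age_grid),
              max(x$age_grid)))
  cat(sprintf("  mu range [%.3f, %.3f], sigma range [%.4f, %.4f]\n",
              min(x$mu), max(x$mu), min(x$sigma), max(x$sigma)))
  invisible(x)
}
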