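#' Prediction-error metrics
#'
#' MAE, RMSE, MBE and R-squared of predicted versus real ages. Sign
#' convention for the bias: `MBE = mean(predicted - real)`, so positive MBE
#' means over-prediction. `R^2 = 1 - SS_res / SS_tot` with real ages as the
#' targets; it is `NA` when the real ages have zero variance.
#'
#' @param predicted,real Equal-length numeric vectors (years). Pairs with
#'   `NA` in either are dropped with a warning.
#' @return A list: `mae`, `rmse`, `mbe`, `r_squared`, `n`.
#' @export
#' @examples
#' compute_metrics(c(10, 20), c(12, 18))  # MAE 2, RMSE 2, MBE 0
compute_metrics <- function(predicted, real) {
  if (length(predicted) != length(real)) {
    stop("predicted and real ages must have equal length", call. = FALSE)
  }
  if (length(predicted) == 0) stop("empty input", call. = FALSE)
  ok <- !is.na(predicted) & !is.na(real)
  if (!all(ok)) {
    warning(sum(!ok), " pair(s) with missing values dropped", call. = FALSE)
    predicted <- predicted[ok]
    real <- real[ok]
    if (length(predicted) == 0) stop("no complete pairs", call. = FALSE)
  }
  res <- predicted - real
  ss_tot <- sum((real - mean(real))^2)
  r2 <- if (ss_tot > 0) 1 - sum(res^2) / ss_tot else NA_real_
  list(mae = mean(abs(res)), rmse = sqrt(mean(res^2)), mbe = mean(res),
       r_squared = r2, n = length(res))
}

#' Random k-fold assignment
#'
#' Seeded uniform permutation split into `k` mutually exclusive, jointly
#' exhaustive folds whose sizes differ by at most one (the first
#' `n %% k` folds take the extra sample).
#'
#' @param n_samples Number of samples.
#' @param k Number of folds (default 10).
#' @param seed Integer seed.
#' @return An object of class `fold_assignment`: `fold` (integer in `1..k`
#'   per sample), `k`, `seed`.
#' @export
make_folds <- function(n_samples, k = 10L, seed = 1L) {
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  if (k > n_samples) {
    stop("k (", k, ") exceeds the number of samples (", n_samples, ")",
         call. = FALSE)
  }
  set.seed(seed)
  sizes <- rep(n_samples %/% k, k)
  extra <- n_samples %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  fold <- integer(n_samples)
  fold[sample.int(n_samples)] <- rep(seq_len(k), times = sizes)
  structure(list(fold = fold, k = as.integer(k), seed = as.integer(seed)),
            class = "fold_assignment")
}

#' k-fold cross-validation of the two-stage clock
#'
#' For each fold, trains the full two-stage pipeline on the remaining folds
#' and predicts the held-out fold, so every sample receives exactly one
#' out-of-fold prediction. When no fixed `cutoff` is given, each fold's
#' training set is split (seeded) into a scan-training and a scan-validation
#' part for [optimize_cutoff()], and the cohort models are then retrained on
#' the full fold training set at the selected cutoff.
#'
#' Folds that fail (e.g. an undersized cohort) are reported in `fold_errors`
#' and the run continues; their samples keep `NA` predictions.
#'
#' @param dataset A [methylation_dataset()] with ages.
#' @param config A [clock_config()].
#' @param k Number of folds (default 10).
#' @param seed Seed for fold assignment and inner splits.
#' @param cutoff Fixed cutoff age; `NULL` scans per fold.
#' @param candidates Cutoff candidates for the scan.
#' @param validation_fraction Fraction of each fold's training set held out
#'   for the cutoff scan (only used when `cutoff` is `NULL`).
#' @return An object of class `evaluation_report`: per-sample `predictions`
#'   (sample_id, fold, real_age, stage1_age, final_age, cohort), `metrics`
#'   (overall / junior / senior, grouped by real age at the cutoff),
#'   `fold_cutoffs`, `fold_errors`, `k`, `seed`.
#' @export
run_cross_validation <- function(dataset, config = clock_config(), k = 10L,
                                 seed = 1L, cutoff = NULL,
                                 candidates = 10:30,
                                 validation_fraction = 0.2) {
  stopifnot(inherits(dataset, "methylation_dataset"))
  if (is.null(dataset$ages)) stop("dataset has no ages", call. = FALSE)
  n <- length(dataset$sample_ids)
  folds <- make_folds(n, k, seed)
  pred <- data.frame(
    sample_id = dataset$sample_ids, fold = folds$fold,
    real_age = dataset$ages, stage1_age = NA_real_, final_age = NA_real_,
    cohort = NA_character_, stringsAsFactors = FALSE
  )
  fold_cutoffs <- rep(NA_real_, k)
  fold_errors <- character(0)
  for (f in seq_len(k)) {
    test_idx <- which(folds$fold == f)
    train_idx <- setdiff(seq_len(n), test_idx)
    res <- tryCatch({
      tr <- subset(dataset, samples = train_idx)
      if (is.null(cutoff)) {
        set.seed(seed * 1000L + f)
        vi <- sample(seq_along(train_idx),
                     max(1L, round(validation_fraction * length(train_idx))))
        scan <- optimize_cutoff(subset(tr, samples = setdiff(
          seq_along(train_idx), vi)), subset(tr, samples = vi),
          candidates, config)
        fold_cut <- scan$selected
      } else {
        fold_cut <- cutoff
      }
      model <- train_two_stage(tr, config, cutoff = fold_cut)
      p <- predict_two_stage(model, subset(dataset, samples = test_idx))
      list(cut = fold_cut, p = p)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      fold_errors <- c(fold_errors,
                       sprintf("fold %d: %s", f, conditionMessage(res)))
      next
    }
    fold_cutoffs[f] <- res$cut
    pred$stage1_age[test_idx] <- res$p$stage1_age
    pred$final_age[test_idx] <- res$p$final_age
    pred$cohort[test_idx] <- res$p$cohort
  }
  ok <- !is.na(pred$final_age)
  overall <- if (any(ok)) compute_metrics(pred$final_age[ok],
                                          pred$real_age[ok]) else NULL
  # per-cohort scoring groups by REAL age at the fold's cutoff (routing still
  # used predicted age); with per-fold cutoffs each sample is grouped by the
  # cutoff of the fold that predicted it
  cut_of <- fold_cutoffs[pred$fold]
  jr <- ok & pred$real_age <= cut_of
  sr <- ok & pred$real_age > cut_of
  metrics <- list(
    overall = overall,
    junior = if (any(jr)) compute_metrics(pred$final_age[jr],
                                          pred$real_age[jr]) else NULL,
    senior = if (any(sr)) compute_metrics(pred$final_age[sr],
                                          pred$real_age[sr]) else NULL
  )
  structure(
    list(predictions = pred, metrics = metrics,
         fold_cutoffs = fold_cutoffs, fold_errors = fold_errors,
         k = as.integer(k), seed = as.integer(seed)),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (seed %d)\n", x$k, x$seed))
  for (g in c("overall", "junior", "senior")) {
    m <- x$metrics[[g]]
    if (is.null(m)) next
    cat(sprintf("  %-7s n=%4d  MAE %.2f  RMSE %.2f  MBE %+.2f\n",
                g, m$n, m$mae, m$rmse, m$mbe))
  }
  if (length(x$fold_errors)) {
    cat("  fold errors:\n   ", paste(x$fold_errors, collapse = "\n    "),
        "\n")
  }
  invisible(x)
}

#' Penalized linear-regression age baseline (LASSO / elastic net)
#'
#' The conventional epigenetic-clock baseline: a linear model of age on site
#' beta values with an elastic-net penalty, fitted with glmnet under the
#' objective `1/(2n) * ||y - X b||^2 + lambda * (l1_ratio * ||b||_1 +
#' (1 - l1_ratio)/2 * ||b||_2^2)` (`l1_ratio = 1` is the LASSO). Missing
#' entries are mean-imputed per site, for the baseline only — the
#' maximum-likelihood clock itself uses site intersection, never imputation.
#'
#' @param train Training [methylation_dataset()] with ages.
#' @param lambda Penalty strength (> 0); the published comparisons use 0.01.
#' @param l1_ratio Elastic-net mixing in \[0, 1\]; 1 = LASSO, the published
#'   elastic-net optimum is 0.72.
#' @param sites Optional site subset (default: all sites).
#' @return An object of class `penalized_baseline`; predict with
#'   [predict.penalized_baseline()]. Predictions are continuous ages, not
#'   restricted to the grid.
#' @export
fit_penalized_baseline <- function(train, lambda = 0.01, l1_ratio = 0.72,
                                   sites = NULL) {
  stopifnot(inherits(train, "methylation_dataset"), lambda > 0,
            l1_ratio >= 0, l1_ratio <= 1)
  if (is.null(train$ages)) stop("training data has no ages", call. = FALSE)
  X <- train$beta
  if (!is.null(sites)) X <- X[, sites, drop = FALSE]
  means <- colMeans(X, na.rm = TRUE)
  for (j in seq_len(ncol(X))) {
    nas <- is.na(X[, j])
    if (any(nas)) X[nas, j] <- means[j]
  }
  usable <- apply(X, 2, function(col) is.finite(col[1]) && sd(col) > 0)
  if (sum(usable) < 2) {
    stop("degenerate design: fewer than 2 non-constant site columns",
         call. = FALSE)
  }
  fit <- glmnet::glmnet(X[, usable, drop = FALSE], train$ages,
                        alpha = l1_ratio, lambda = lambda,
                        standardize = TRUE)
  structure(
    list(fit = fit, sites = colnames(X)[usable], means = means[usable],
         lambda = lambda, l1_ratio = l1_ratio),
    class = "penalized_baseline"
  )
}

#' Predict ages with a penalized baseline
#'
#' @param object A [fit_penalized_baseline()] model.
#' @param dataset A [methylation_dataset()] containing the model's sites
#'   (missing entries are imputed with the training means).
#' @param ... Unused.
#' @return Numeric vector of continuous predicted ages.
#' @export
predict.penalized_baseline <- function(object, dataset, ...) {
  stopifnot(inherits(dataset, "methylation_dataset"))
  miss <- setdiff(object$sites, dataset$site_ids)
  if (length(miss) > 0) {
    stop("dataset lacks baseline sites: ",
         paste(head(miss, 5), collapse = ", "), call. = FALSE)
  }
  X <- dataset$beta[, object$sites, drop = FALSE]
  for (j in seq_len(ncol(X))) {
    nas <- is.na(X[, j])
    if (any(nas)) X[nas, j] <- object$means[j]
  }
  as.vector(predict(object$fit, newx = X, s = object$lambda))
}

#' Residual-trend diagnostics
#'
#' Summarizes prediction bias as a function of real age: the least-squares
#' slope and Pearson correlation of the residuals (predicted - real) against
#' real age, plus a LOWESS curve of residuals versus real age for plotting.
#' An unbiased clock shows near-zero slope and correlation; linear-regression
#' clocks typically show the classic negative slope (over-predicting the
#' young, under-predicting the old).
#'
#' @param predicted,real Equal-length numeric vectors of ages (NA pairs
#'   dropped).
#' @param tau LOWESS fraction for the residual curve.
#' @return A list: `slope`, `correlation`, `mean_residual`, and `curve`
#'   (data.frame `age`, `residual`).
#' @export
residual_diagnostics <- function(predicted, real, tau = 0.7) {
  ok <- !is.na(predicted) & !is.na(real)
  predicted <- predicted[ok]
  real <- real[ok]
  if (length(real) < 10) {
    stop("residual diagnostics need at least 10 samples", call. = FALSE)
  }
  res <- predicted - real
  slope <- if (sd(real) > 0) unname(coef(lm(res ~ real))[2]) else NA_real_
  corr <- if (sd(real) > 0 && sd(res) > 0) cor(res, real) else 0
  grid <- seq(min(real), max(real), length.out = 101)
  smooth <- if (diff(range(real)) > 0) {
    predict(fit_lowess(real, res, tau = tau), grid)
  } else {
    rep(mean(res), length(grid))
  }
  list(slope = slope, correlation = corr, mean_residual = mean(res),
       curve = data.frame(age = grid, residual = smooth))
}
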