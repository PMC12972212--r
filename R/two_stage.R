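#' Train the first-stage (full-population) reference
#'
#' Computes Spearman correlations on the full training population, screens at
#' `|rho| >= min_abs_rho`, selects the top `n_sites` sites, and builds the
#' stage-1 reference matrix. The screened site set is attached as attribute
#' `"screened_sites"`; cohort-specific re-selection in stage 2 re-ranks
#' within this screened universe rather than over all sites (screening exists
#' precisely to avoid re-ranking an array-scale site universe per cohort).
#'
#' @param train Training [methylation_dataset()] with ages.
#' @param config A [clock_config()].
#' @return A `reference_matrix` with attribute `screened_sites`.
#' @export
train_stage1 <- function(train, config = clock_config()) {
  corr <- spearman_correlations(train)
  screened <- screen_sites(corr, config$min_abs_rho)
  pool <- corr[corr$site_id %in% screened, , drop = FALSE]
  if (nrow(pool) == 0) pool <- corr # screen emptied: select from what exists
  top <- select_top_sites(pool, config$n_sites)
  if (length(top) == 0) {
    stop("too few usable sites to train a reference", call. = FALSE)
  }
  ref <- build_reference_matrix(train, top, config)
  attr(ref, "screened_sites") <- screened
  ref
}

#' Train junior and senior cohort references
#'
#' Splits the training data by real age at `cutoff_age` (junior: real age
#' `<= cutoff_age`), then, independently per cohort, recomputes Spearman
#' correlations within the cohort, screens, selects the top sites and builds
#' a cohort reference matrix. Each cohort may therefore end up with a
#' different site list.
#'
#' @param train Training [methylation_dataset()] with ages.
#' @param cutoff_age Split age in years.
#' @param config A [clock_config()].
#' @param universe Optional site ids restricting the candidate pool (the
#'   stage-1 screened set, typically). `NULL` uses all sites.
#' @return A list with `reference_matrix` elements `junior` and `senior`.
#' @export
train_cohort_models <- function(train, cutoff_age, config = clock_config(),
                                universe = NULL) {
  stopifnot(inherits(train, "methylation_dataset"))
  if (is.null(train$ages)) stop("training data has no ages", call. = FALSE)
  idx_j <- which(train$ages <= cutoff_age)
  idx_s <- which(train$ages > cutoff_age)
  if (length(idx_j) < config$min_cohort_size) {
    stop("junior cohort has ", length(idx_j), " samples at cutoff ",
         cutoff_age, " (need >= ", config$min_cohort_size, ")",
         call. = FALSE)
  }
  if (length(idx_s) < config$min_cohort_size) {
    stop("senior cohort has ", length(idx_s), " samples at cutoff ",
         cutoff_age, " (need >= ", config$min_cohort_size, ")",
         call. = FALSE)
  }
  fit_cohort <- function(idx, label) {
    coh <- subset(train, samples = idx,
                  sites = if (is.null(universe)) NULL else
                    match(intersect(universe, train$site_ids),
                          train$site_ids))
    corr <- spearman_correlations(coh)
    screened <- suppressWarnings(screen_sites(corr, config$min_abs_rho))
    pool <- corr[corr$site_id %in% screened, , drop = FALSE]
    if (nrow(pool) == 0) {
      warning(label, " cohort: no sites pass the screen; ",
              "selecting from all candidate sites", call. = FALSE)
      pool <- corr
    }
    top <- select_top_sites(pool, config$n_sites)
    build_reference_matrix(coh, top, config)
  }
  list(junior = fit_cohort(idx_j, "junior"),
       senior = fit_cohort(idx_s, "senior"))
}

#' Scan junior-cohort cutoff ages and pick the least-biased one
#'
#' For every candidate cutoff, trains cohort models on `train` (splitting at
#' real age `<=` candidate), generates full two-stage predictions for
#' `validation` (routing at stage-1 age `<=` candidate), and records MAE,
#' RMSE and MBE. The selected cutoff attains the smallest `|MBE|` — low bias
#' being the framework's defining advantage — with ties broken toward the
#' smallest candidate. Candidates whose cohorts are too small are skipped
#' with a warning.
#'
#' @param train Training [methylation_dataset()] with ages.
#' @param validation Held-out [methylation_dataset()] with ages, scored per
#'   candidate.
#' @param candidates Integer cutoff candidates (default 10:30).
#' @param config A [clock_config()].
#' @param stage1 Optional pre-trained stage-1 reference (with
#'   `screened_sites` attribute); trained on `train` if `NULL`.
#' @return An object of class `cutoff_scan`: data.frame `scan` (cutoff, mae,
#'   rmse, mbe) and `selected`.
#' @export
optimize_cutoff <- function(train, validation, candidates = 10:30,
                            config = clock_config(), stage1 = NULL) {
  stopifnot(length(candidates) >= 1)
  if (is.null(validation$ages)) {
    stop("validation data has no ages", call. = FALSE)
  }
  if (is.null(stage1)) stage1 <- train_stage1(train, config)
  universe <- attr(stage1, "screened_sites")
  rows <- lapply(candidates, function(cand) {
    cohorts <- tryCatch(
      train_cohort_models(train, cand, config, universe = universe),
      error = function(e) {
        warning("cutoff ", cand, " skipped: ", conditionMessage(e),
                call. = FALSE)
        NULL
      }
    )
    if (is.null(cohorts)) return(NULL)
    model <- new_two_stage_model(stage1, cohorts$junior, cohorts$senior,
                                 cand, config)
    pred <- predict_two_stage(model, validation)
    m <- compute_metrics(pred$final_age, validation$ages)
    data.frame(cutoff = cand, mae = m$mae, rmse = m$rmse, mbe = m$mbe)
  })
  scan <- do.call(rbind, rows)
  if (is.null(scan) || nrow(scan) == 0) {
    stop("no cutoff candidate could be evaluated", call. = FALSE)
  }
  best <- scan$cutoff[order(abs(scan$mbe), scan$cutoff)][1]
  structure(list(scan = scan, selected = best), class = "cutoff_scan")
}

#' @export
print.cutoff_scan <- function(x, ...) {
  cat(sprintf("Cutoff scan over %d candidates; selected cutoff = %d (|MBE| = %.3f)\n",
              nrow(x$scan), x$selected,
              abs(x$scan$mbe[x$scan$cutoff == x$selected])))
  print(x$scan, row.names = FALSE, digits = 4)
  invisible(x)
}

new_two_stage_model <- function(stage1, junior, senior, cutoff_age, config,
                                sex_label = "mixed", cutoff_scan = NULL) {
  structure(
    list(stage1 = stage1, junior = junior, senior = senior,
         cutoff_age = as.numeric(cutoff_age),
         routing_threshold = as.numeric(cutoff_age),
         config = config, sex_label = sex_label, cutoff_scan = cutoff_scan),
    class = "two_stage_model"
  )
}

#' Train a complete two-stage clock
#'
#' Stage 1 trains a full-population reference; the junior/senior cutoff is
#' either given (`cutoff`) or chosen by [optimize_cutoff()] on a held-out
#' `validation` set; stage 2 then trains cohort references on `train` split
#' at the chosen cutoff. The routing threshold used at prediction time equals
#' the training cutoff (at the published optimum of 25 this is the familiar
#' 25-or-younger / 26-or-older routing).
#'
#' @param train Training [methylation_dataset()] with ages.
#' @param config A [clock_config()].
#' @param cutoff Fixed cutoff age; `NULL` to scan.
#' @param validation Held-out data for the cutoff scan (required when
#'   `cutoff` is `NULL`).
#' @param candidates Cutoff candidates for the scan.
#' @return An object of class `two_stage_model` with fields `stage1`,
#'   `junior`, `senior`, `cutoff_age`, `routing_threshold`, `config`,
#'   `sex_label` and (when scanned) `cutoff_scan`.
#' @export
#' @examples
#' sim <- simulate_dataset(sim_config(n_samples = 300, n_sites = 30,
#'                                    curve_family = "piecewise", seed = 3))
#' model <- train_two_stage(sim$dataset, cutoff = 20)
#' model
train_two_stage <- function(train, config = clock_config(), cutoff = NULL,
                            validation = NULL, candidates = 10:30) {
  stage1 <- train_stage1(train, config)
  scan <- NULL
  if (is.null(cutoff)) {
    if (is.null(validation)) {
      stop("either a fixed `cutoff` or a `validation` dataset for the scan ",
           "is required", call. = FALSE)
    }
    scan <- optimize_cutoff(train, validation, candidates, config,
                            stage1 = stage1)
    cutoff <- scan$selected
  }
  cohorts <- train_cohort_models(train, cutoff, config,
                                 universe = attr(stage1, "screened_sites"))
  new_two_stage_model(stage1, cohorts$junior, cohorts$senior, cutoff, config,
                      cutoff_scan = scan)
}

#' @export
print.two_stage_model <- function(x, ...) {
  cat(sprintf("Two-stage clock (%s), cutoff age = %g, routing at <= %g\n",
              x$sex_label, x$cutoff_age, x$routing_threshold))
  cat(sprintf("  stage 1: %d sites; junior: %d sites; senior: %d sites\n",
              length(x$stage1$site_ids), length(x$junior$site_ids),
              length(x$senior$site_ids)))
  cat(sprintf("  family = %s, tau = %g\n", x$config$family, x$config$tau))
  invisible(x)
}

#' Two-stage age prediction
#'
#' Every sample first receives a stage-1 maximum-likelihood age from the
#' full-population reference; samples with stage-1 age at or below the
#' routing threshold are routed to the junior reference, the rest to the
#' senior reference, and the routed cohort model produces the final age.
#' Samples misrouted by a stage-1 error across the boundary are accepted
#' as-is (no iterative re-routing). Samples with no usable site overlap are
#' recorded as failed (`NA`) predictions; the rest proceed.
#'
#' @param model A [train_two_stage()] model.
#' @param dataset A [methylation_dataset()] (ages not required).
#' @param family Likelihood family override (default: the model's).
#' @return A data.frame: `sample_id`, `stage1_age`, `final_age`, `cohort`
#'   (`"junior"`/`"senior"`), `n_sites_used`, `max_log_likelihood`.
#' @export
predict_two_stage <- function(model, dataset, family = NULL) {
  stopifnot(inherits(model, "two_stage_model"),
            inherits(dataset, "methylation_dataset"))
  config <- model$config
  if (is.null(family)) family <- config$family
  s1 <- predict_ages(model$stage1, dataset, family, config)
  junior <- !is.na(s1$age) & s1$age <= model$routing_threshold
  out <- data.frame(
    sample_id = dataset$sample_ids,
    stage1_age = s1$age,
    final_age = NA_real_,
    cohort = ifelse(is.na(s1$age), NA_character_,
                    ifelse(junior, "junior", "senior")),
    n_sites_used = NA_integer_,
    max_log_likelihood = NA_real_,
    stringsAsFactors = FALSE
  )
  for (label in c("junior", "senior")) {
    idx <- which(!is.na(out$cohort) & out$cohort == label)
    if (length(idx) == 0) next
    p <- predict_ages(model[[label]], subset(dataset, samples = idx),
                      family, config)
    out$final_age[idx] <- p$age
    out$n_sites_used[idx] <- p$n_sites_used
    out$max_log_likelihood[idx] <- p$max_log_likelihood
  }
  out
}

#' Train sex-specific two-stage clocks
#'
#' Runs the full two-stage pipeline independently on the male and the female
#' subset of the training data (and of the validation data, when a cutoff
#' scan is requested). Samples of unknown sex are excluded with a warning.
#'
#' @inheritParams train_two_stage
#' @return A list with `two_stage_model` elements `male` and `female`
#'   (`sex_label` set accordingly).
#' @export
train_sex_specific <- function(train, config = clock_config(), cutoff = NULL,
                               validation = NULL, candidates = 10:30) {
  stopifnot(inherits(train, "methylation_dataset"))
  if (any(train$sex == "unknown")) {
    warning(sum(train$sex == "unknown"),
            " sample(s) of unknown sex excluded from sex-specific training",
            call. = FALSE)
  }
  fit_one <- function(lab) {
    idx <- which(train$sex == lab)
    if (length(idx) < config$min_cohort_size) {
      stop("sex group '", lab, "' has ", length(idx),
           " samples (need >= ", config$min_cohort_size, ")", call. = FALSE)
    }
    val <- NULL
    if (!is.null(validation)) {
      vidx <- which(validation$sex == lab)
      if (length(vidx) > 0) val <- subset(validation, samples = vidx)
    }
    m <- train_two_stage(subset(train, samples = idx), config,
                         cutoff = cutoff, validation = val,
                         candidates = candidates)
    m$sex_label <- lab
    m
  }
  list(male = fit_one("male"), female = fit_one("female"))
}
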