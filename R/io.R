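#' Read a beta-value matrix from delimited text
#'
#' Expects a header of ids and a first column of ids; empty cells and `NA`
#' become missing values. Internally the matrix is always oriented samples x
#' sites; use `orientation = "sites_by_samples"` for transposed files. The
#' delimiter is sniffed from the header (tab or comma).
#'
#' @param path File path (TSV or CSV).
#' @param orientation `"samples_by_sites"` (default) or
#'   `"sites_by_samples"`.
#' @return A [methylation_dataset()] without ages/sex (attach them with
#'   [read_metadata()]).
#' @export
read_beta_matrix <- function(path,
                             orientation = c("samples_by_sites",
                                             "sites_by_samples")) {
  orientation <- match.arg(orientation)
  sep <- sniff_sep(path)
  df <- read.table(path, header = TRUE, sep = sep, row.names = 1,
                   check.names = FALSE, stringsAsFactors = FALSE,
                   na.strings = c("NA", ""))
  m <- as.matrix(df)
  if (!is.numeric(m)) {
    stop("non-numeric cells in beta matrix: ", path, call. = FALSE)
  }
  if (orientation == "sites_by_samples") m <- t(m)
  methylation_dataset(m)
}

sniff_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

#' Write a beta-value matrix as TSV
#'
#' Samples as rows, probe ids as columns, missing entries as empty cells.
#'
#' @param dataset A [methylation_dataset()] (or a bare numeric matrix).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(dataset, path) {
  m <- if (inherits(dataset, "methylation_dataset")) dataset$beta else dataset
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' Read sample metadata (ages and sex) and join it to a dataset
#'
#' Expects columns `sample_id`, `age`, `sex` (TSV or CSV). Sex is normalized
#' case-insensitively from `{M, F, male, female}`; anything else becomes
#' `"unknown"`. Ages must be non-negative.
#'
#' @param path Metadata file path.
#' @param dataset Optional [methylation_dataset()] to attach the metadata to.
#' @param strict When a dataset is given: if `TRUE` (default), samples in the
#'   matrix that are absent from the metadata raise an error listing the
#'   missing ids; if `FALSE`, those samples are dropped with a warning.
#' @return If `dataset` is `NULL`, a data.frame (`sample_id`, `age`, `sex`);
#'   otherwise the dataset with `ages` and `sex` filled in (and possibly
#'   fewer samples in lenient mode).
#' @export
read_metadata <- function(path, dataset = NULL, strict = TRUE) {
  sep <- sniff_sep(path)
  df <- read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                   stringsAsFactors = FALSE, na.strings = c("NA", ""))
  need <- c("sample_id", "age", "sex")
  if (!all(need %in% names(df))) {
    stop("metadata must have columns sample_id, age, sex; found: ",
         paste(names(df), collapse = ", "), call. = FALSE)
  }
  df$age <- as.numeric(df$age)
  if (any(!is.na(df$age) & df$age < 0)) {
    stop("negative age in metadata for sample(s): ",
         paste(df$sample_id[!is.na(df$age) & df$age < 0], collapse = ", "),
         call. = FALSE)
  }
  df$sex <- normalize_sex(df$sex, nrow(df))
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample ids in metadata", call. = FALSE)
  }
  if (is.null(dataset)) return(df[, need])
  stopifnot(inherits(dataset, "methylation_dataset"))
  hit <- match(dataset$sample_ids, df$sample_id)
  if (anyNA(hit)) {
    absent <- dataset$sample_ids[is.na(hit)]
    if (strict) {
      stop("samples missing from metadata: ",
           paste(absent, collapse = ", "), call. = FALSE)
    }
    warning(length(absent), " sample(s) without metadata dropped",
            call. = FALSE)
    dataset <- subset(dataset, samples = which(!is.na(hit)))
    hit <- hit[!is.na(hit)]
  }
  methylation_dataset(dataset$beta, ages = df$age[hit], sex = df$sex[hit])
}

#' Write two-stage predictions as TSV
#'
#' @param predictions A [predict_two_stage()] data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  write.table(predictions, path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "NA")
  invisible(path)
}

MODEL_SCHEMA_VERSION <- "1.0"

reference_to_list <- function(ref) {
  list(site_ids = ref$site_ids, age_grid = ref$age_grid,
       mu = unname(ref$mu), sigma = unname(ref$sigma))
}

reference_from_list <- function(x) {
  mu <- do.call(rbind, lapply(x$mu, as.numeric))
  sigma <- do.call(rbind, lapply(x$sigma, as.numeric))
  site_ids <- as.character(unlist(x$site_ids))
  grid <- as.integer(unlist(x$age_grid))
  dimnames(mu) <- dimnames(sigma) <- list(site_ids, as.character(grid))
  structure(list(site_ids = site_ids, age_grid = grid, mu = mu,
                 sigma = sigma),
            class = "reference_matrix")
}

#' Save a trained two-stage model as versioned JSON
#'
#' The file stores the schema version, the full configuration, the cutoff and
#' routing threshold, and the three reference matrices as explicit per-site
#' grids of `mu` and `sigma` (full double precision), so prediction from a
#' reloaded model is bit-identical and independent of the smoothing
#' implementation.
#'
#' @param model A [train_two_stage()] model.
#' @param path Output path (`.json`).
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "two_stage_model"))
  if (is.null(model$stage1) || is.null(model$junior) ||
      is.null(model$senior)) {
    stop("model incomplete: all three reference matrices are required",
         call. = FALSE)
  }
  payload <- list(
    schema_version = MODEL_SCHEMA_VERSION,
    sex_label = model$sex_label,
    cutoff_age = model$cutoff_age,
    routing_threshold = model$routing_threshold,
    config = unclass(model$config),
    stage1 = reference_to_list(model$stage1),
    junior = reference_to_list(model$junior),
    senior = reference_to_list(model$senior),
    cutoff_scan = if (!is.null(model$cutoff_scan)) {
      list(scan = model$cutoff_scan$scan,
           selected = model$cutoff_scan$selected)
    }
  )
  # 17 significant digits: doubles survive the text round trip bit-exactly
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' Load a two-stage model saved by [save_model()]
#'
#' Refuses files whose schema version differs from the package's (no silent
#' coercion between schema generations).
#'
#' @param path Model JSON path.
#' @return A `two_stage_model`.
#' @export
load_model <- function(path) {
  payload <- tryCatch(
    jsonlite::read_json(path, simplifyVector = FALSE),
    error = function(e) {
      stop("cannot parse model file '", path, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  if (is.null(payload$schema_version) ||
      !identical(payload$schema_version, MODEL_SCHEMA_VERSION)) {
    stop("model schema version mismatch: file has '",
         payload$schema_version %||% "<none>", "', this package reads '",
         MODEL_SCHEMA_VERSION, "'", call. = FALSE)
  }
  cfg <- payload$config
  config <- clock_config(
    tau = cfg$tau, n_sites = cfg$n_sites, min_abs_rho = cfg$min_abs_rho,
    family = cfg$family, sigma_floor = cfg$sigma_floor,
    min_bin_size = cfg$min_bin_size, n_robust_iters = cfg$n_robust_iters,
    x_eps = cfg$x_eps, feasibility_fraction = cfg$feasibility_fraction,
    min_cohort_size = cfg$min_cohort_size, min_sites = cfg$min_sites,
    age_grid = as.integer(unlist(cfg$age_grid))
  )
  scan <- NULL
  if (!is.null(payload$cutoff_scan)) {
    scan_df <- do.call(rbind, lapply(payload$cutoff_scan$scan, function(r) {
      data.frame(cutoff = r$cutoff, mae = r$mae, rmse = r$rmse, mbe = r$mbe)
    }))
    scan <- structure(list(scan = scan_df,
                           selected = payload$cutoff_scan$selected),
                      class = "cutoff_scan")
  }
  model <- new_two_stage_model(
    reference_from_list(payload$stage1),
    reference_from_list(payload$junior),
    reference_from_list(payload$senior),
    payload$cutoff_age, config,
    sex_label = payload$sex_label %||% "mixed",
    cutoff_scan = scan
  )
  model$routing_threshold <- as.numeric(payload$routing_threshold)
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a
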