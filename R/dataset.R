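#' Methylation dataset
#'
#' Container for a samples-by-sites matrix of methylation beta values plus
#' per-sample metadata. Beta values are fractions in \[0, 1\]; missing
#' measurements are `NA` (an explicit mask, never a sentinel value).
#'
#' @param beta Numeric matrix, samples in rows, CpG sites in columns. Row
#'   names are sample ids, column names are probe ids (e.g. "cg00000029").
#' @param ages Optional numeric vector of chronological ages in years, one per
#'   sample. May be `NULL` for prediction-only data.
#' @param sex Optional per-sample sex, normalized case-insensitively from
#'   `{M, F, male, female}`; anything else becomes `"unknown"`.
#'
#' @return An object of class `methylation_dataset` with elements `beta`,
#'   `sample_ids`, `site_ids`, `ages`, `sex`.
#' @export
#' @examples
#' m <- matrix(c(0.1, 0.9, NA, 0.5), 2, 2,
#'             dimnames = list(c("s1", "s2"), c("cg01", "cg02")))
#' methylation_dataset(m, ages = c(30, 60), sex = c("F", "MALE"))
methylation_dataset <- function(beta, ages = NULL, sex = NULL) {
  if (!is.matrix(beta) || !is.numeric(beta)) {
    stop("`beta` must be a numeric matrix (samples x sites)", call. = FALSE)
  }
  if (is.null(rownames(beta))) {
    rownames(beta) <- sprintf("sample_%d", seq_len(nrow(beta)))
  }
  if (is.null(colnames(beta))) {
    stop("`beta` must have column names (CpG probe ids)", call. = FALSE)
  }
  sample_ids <- rownames(beta)
  site_ids <- colnames(beta)
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(site_ids)) {
    stop("duplicate site ids: ",
         paste(unique(site_ids[duplicated(site_ids)]), collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!is.na(beta) & (beta < 0 | beta > 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "beta value out of [0,1] at sample '%s', site '%s' (value %g)",
      sample_ids[bad[1, 1]], site_ids[bad[1, 2]], beta[bad[1, , drop = FALSE]]
    ), call. = FALSE)
  }
  if (!is.null(ages)) {
    if (length(ages) != nrow(beta)) {
      stop("`ages` must have one entry per sample", call. = FALSE)
    }
    ages <- as.numeric(ages)
    if (any(!is.na(ages) & ages < 0)) {
      stop("negative age in metadata", call. = FALSE)
    }
  }
  sex <- normalize_sex(sex, nrow(beta))
  structure(
    list(beta = beta, sample_ids = sample_ids, site_ids = site_ids,
         ages = ages, sex = sex),
    class = "methylation_dataset"
  )
}

normalize_sex <- function(sex, n) {
  if (is.null(sex)) return(rep("unknown", n))
  if (length(sex) != n) stop("`sex` must have one entry per sample", call. = FALSE)
  s <- tolower(trimws(as.character(sex)))
  out <- rep("unknown", n)
  out[s %in% c("m", "male")] <- "male"
  out[s %in% c("f", "female")] <- "female"
  out
}

#' @export
print.methylation_dataset <- function(x, ...) {
  cat(sprintf("Methylation dataset: %d samples x %d sites\n",
              nrow(x$beta), ncol(x$beta)))
  cat(sprintf("  missing entries: %d (%.2f%%)\n", sum(is.na(x$beta)),
              100 * mean(is.na(x$beta))))
  if (!is.null(x$ages)) {
    cat(sprintf("  ages: %g .. %g years\n", min(x$ages), max(x$ages)))
  } else {
    cat("  ages: (none)\n")
  }
  cat(sprintf("  sex: %s\n",
              paste(sprintf("%s=%d", names(table(x$sex)), table(x$sex)),
                    collapse = ", ")))
  invisible(x)
}

#' Subset a methylation dataset by samples and/or sites
#'
#' @param x A `methylation_dataset`.
#' @param samples Sample indices, ids or logical mask (default: all).
#' @param sites Site indices, ids or logical mask (default: all).
#' @param ... Unused.
#' @return A `methylation_dataset` restricted to the selection.
#' @export
subset.methylation_dataset <- function(x, samples = NULL, sites = NULL, ...) {
  if (is.null(samples)) samples <- seq_along(x$sample_ids)
  if (is.null(sites)) sites <- seq_along(x$site_ids)
  beta <- x$beta[samples, sites, drop = FALSE]
  methylation_dataset(
    beta,
    ages = if (!is.null(x$ages)) x$ages[match(rownames(beta), x$sample_ids)],
    sex = x$sex[match(rownames(beta), x$sample_ids)]
  )
}
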