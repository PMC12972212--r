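#' Spearman correlation of methylation with age, per CpG site
#'
#' Computes the Spearman rank correlation between chronological age and
#' methylation for every site, on pairwise-complete observations with average
#' (midrank) handling of ties. Spearman is used because the methylation-age
#' relationship is monotone but typically nonlinear (saturating), which a rank
#' correlation captures robustly.
#'
#' Sites with fewer than 3 usable (non-missing) pairs get `rho = NA` and are
#' excluded from downstream screening/selection.
#'
#' @param dataset A [methylation_dataset()] with ages.
#' @return A data.frame with columns `site_id`, `rho`, `n_used`.
#' @export
#' @examples
#' m <- matrix(seq(0.1, 0.5, by = 0.1), 5, 1, dimnames = list(NULL, "cg01"))
#' spearman_correlations(methylation_dataset(m, ages = 1:5))
spearman_correlations <- function(dataset) {
  stopifnot(inherits(dataset, "methylation_dataset"))
  if (is.null(dataset$ages)) {
    stop("dataset has no ages; correlations with age are undefined",
         call. = FALSE)
  }
  n_used <- colSums(!is.na(dataset$beta) & !is.na(dataset$ages))
  suppressWarnings(
    rho <- as.vector(cor(dataset$beta, dataset$ages, method = "spearman",
                         use = "pairwise.complete.obs"))
  )
  rho[n_used < 3L] <- NA_real_
  data.frame(site_id = dataset$site_ids, rho = rho,
             n_used = as.integer(n_used), stringsAsFactors = FALSE)
}

#' Screen sites by absolute Spearman correlation
#'
#' Retains sites with `|rho| >= min_abs_rho` (default 0.60, the published
#' pre-filter that narrows a 450K-scale array to the age-relevant sites).
#' Sites with undefined `rho` are dropped.
#'
#' @param correlations Output of [spearman_correlations()].
#' @param min_abs_rho Threshold in \[0, 1\].
#' @return Character vector of retained site ids (possibly empty, with a
#'   warning).
#' @export
screen_sites <- function(correlations, min_abs_rho = 0.60) {
  stopifnot(is.data.frame(correlations),
            all(c("site_id", "rho") %in% names(correlations)),
            min_abs_rho >= 0, min_abs_rho <= 1)
  keep <- !is.na(correlations$rho) & abs(correlations$rho) >= min_abs_rho
  out <- correlations$site_id[keep]
  if (length(out) == 0) {
    warning("no sites pass the |rho| >= ", min_abs_rho, " screen",
            call. = FALSE)
  }
  out
}

#' Select the top age-correlated sites
#'
#' Orders sites by `|rho|` descending (ties broken by site id, ascending) and
#' returns the first `k`. The published clock uses `k = 16`.
#'
#' @param correlations Output of [spearman_correlations()], possibly already
#'   restricted to a screened subset.
#' @param k Number of sites to select (default 16).
#' @return Character vector of up to `k` site ids in rank order. If fewer
#'   than `k` sites have defined `rho`, all are returned with a warning.
#' @export
select_top_sites <- function(correlations, k = 16L) {
  stopifnot(is.data.frame(correlations),
            all(c("site_id", "rho") %in% names(correlations)))
  if (!is.numeric(k) || length(k) != 1L || k < 1) {
    stop("invalid argument: k must be a positive integer", call. = FALSE)
  }
  ok <- correlations[!is.na(correlations$rho), , drop = FALSE]
  ord <- order(-abs(ok$rho), ok$site_id)
  ids <- ok$site_id[ord]
  if (length(ids) < k) {
    warning("only ", length(ids), " sites available for selection (k = ", k,
            ")", call. = FALSE)
    return(ids)
  }
  ids[seq_len(k)]
}
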