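#' Fit a LOWESS smoother (tricube local-linear regression)
#'
#' Locally weighted scatterplot smoothing as used for the clock's reference
#' curves: at each distinct observed `x`, a weighted linear regression over
#' the `ceiling(tau * n)` nearest points, with tricube weights
#' `(1 - (d/h)^3)^3` scaled by the window radius `h`. Evaluation at new
#' points interpolates linearly between the fitted values at the distinct
#' observed `x`, with constant extrapolation (clamping) beyond the observed
#' range.
#'
#' The local fit falls back to a weighted mean when the windowed design is
#' degenerate (e.g. all in-window `x` identical). Optional robustifying
#' iterations reweight by Tukey's bisquare of the residuals; the default is
#' plain (non-robust) tricube weights.
#'
#' @param x,y Numeric vectors of equal length; pairs with `NA` are dropped.
#' @param tau Smoothing fraction in (0, 1]: fraction of points per window.
#' @param n_robust_iters Number of robustifying iterations (default 0).
#' @return An object of class `lowess_fit` with fields `x` (distinct sorted
#'   abscissae) and `fitted`; evaluate with [predict()].
#' @export
#' @examples
#' f <- fit_lowess(1:20, 2 * (1:20), tau = 0.5)
#' predict(f, c(3.5, 100))  # interpolated; clamped beyond the range
fit_lowess <- function(x, y, tau = 0.7, n_robust_iters = 0L) {
  stopifnot(length(x) == length(y), is.numeric(x), is.numeric(y),
            tau > 0, tau <= 1)
  keep <- is.finite(x) & !is.na(y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 3L) {
    stop("insufficient data: LOWESS needs at least 3 points, got ", n,
         call. = FALSE)
  }
  if (diff(range(x)) == 0) {
    stop("degenerate input: all x values identical", call. = FALSE)
  }
  k <- max(2L, min(n, ceiling(tau * n)))
  ux <- sort(unique(x))
  rw <- rep(1, n) # robustness weights
  fitted_at <- function(x0, rw) {
    d <- abs(x - x0)
    h <- sort(d, partial = k)[k]
    if (h == 0) {
      w <- as.numeric(d == 0) * rw
      return(sum(w * y) / sum(w))
    }
    w <- numeric(n)
    inw <- d < h
    w[inw] <- (1 - (d[inw] / h)^3)^3
    w <- w * rw
    sw <- sum(w)
    if (sw <= 0) { # all robustness weight removed; fall back to tricube only
      w[inw] <- (1 - (d[inw] / h)^3)^3
      sw <- sum(w)
    }
    xw <- sum(w * x) / sw
    sxx <- sum(w * (x - xw)^2)
    yw <- sum(w * y) / sw
    if (sxx <= .Machine$double.eps * max(1, x0^2)) return(yw)
    b1 <- sum(w * (x - xw) * (y - yw)) / sxx
    yw + b1 * (x0 - xw)
  }
  fv <- vapply(ux, fitted_at, numeric(1), rw = rw)
  iter <- 0L
  while (iter < n_robust_iters) {
    res <- y - fv[match(x, ux)]
    s <- median(abs(res))
    if (s <= 0) break
    u <- res / (6 * s)
    rw <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    fv <- vapply(ux, fitted_at, numeric(1), rw = rw)
    iter <- iter + 1L
  }
  structure(list(x = ux, fitted = fv, tau = tau, n = n), class = "lowess_fit")
}

#' Evaluate a fitted LOWESS smoother
#'
#' @param object A `lowess_fit`.
#' @param newx Points at which to evaluate.
#' @param ... Unused.
#' @return Smoothed values: linear interpolation between fitted values at the
#'   observed abscissae, constant beyond the observed range.
#' @export
predict.lowess_fit <- function(object, newx, ...) {
  if (length(object$x) == 1L) return(rep(object$fitted, length(newx)))
  approx(object$x, object$fitted, xout = newx, rule = 2)$y
}

#' @export
print.lowess_fit <- function(x, ...) {
  cat(sprintf("LOWESS fit: %d points, %d distinct x, tau = %g\n",
              x$n, length(x$x), x$tau))
  invisible(x)
}
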