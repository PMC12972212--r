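# Independent oracles, deliberately implemented through different routes than
# the package code they check.

# Spearman: explicit midranks, then the Pearson product-moment formula.
oracle_spearman <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  rx <- rank(x[ok], ties.method = "average")
  ry <- rank(y[ok], ties.method = "average")
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Tricube weighted least squares at a single evaluation point, via lm().
# Window rule matches the documented smoother semantics: the ceiling(tau*n)
# nearest points define the radius h; weights (1-(d/h)^3)^3 for d < h.
oracle_tricube_wls <- function(x, y, x0, tau) {
  n <- length(x)
  k <- max(2L, min(n, ceiling(tau * n)))
  d <- abs(x - x0)
  h <- sort(d, partial = k)[k]
  if (h == 0) return(mean(y[d == 0]))
  w <- ifelse(d < h, (1 - (d / h)^3)^3, 0)
  if (sum(w > 0 & !duplicated(x)) < 2) return(sum(w * y) / sum(w))
  fit <- lm(y ~ x, weights = w)
  unname(predict(fit, newdata = data.frame(x = x0)))
}

# Metrics recomputed longhand.
oracle_metrics <- function(p, r) {
  list(mae = sum(abs(p - r)) / length(p),
       rmse = sqrt(sum((p - r)^2) / length(p)),
       mbe = sum(p - r) / length(p))
}

# Tiny deterministic dataset: linear trends, optional noise.
make_linear_dataset <- function(n = 60, p = 6, informative = 4, noise = 0,
                                seed = 42, age_min = 0, age_max = 100) {
  set.seed(seed)
  ages <- sample(age_min:age_max, n, replace = TRUE)
  slopes <- c(seq(0.3, 0.6, length.out = informative),
              rep(0, p - informative))
  beta <- sapply(seq_len(p), function(j) {
    mu <- 0.2 + slopes[j] * ages / age_max
    pmin(pmax(mu + rnorm(n, 0, noise), 0), 1)
  })
  colnames(beta) <- sprintf("cg%08d", seq_len(p))
  rownames(beta) <- sprintf("s%03d", seq_len(n))
  methylation_dataset(beta, ages = ages)
}
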