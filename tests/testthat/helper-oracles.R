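# Independent brute-force oracles and small fixture builders used across the
# suite. These deliberately avoid the package's own code paths.

# Pearson correlation written out from the covariance definition.
oracle_pearson <- function(x, y) {
  n <- length(x)
  cov_xy <- sum((x - mean(x)) * (y - mean(y))) / (n - 1)
  cov_xy / sqrt(sum((x - mean(x))^2) / (n - 1)) / sqrt(sum((y - mean(y))^2) / (n - 1))
}

oracle_r2 <- function(obs, pred) 1 - sum((pred - obs)^2) / sum((obs - mean(obs))^2)

oracle_rmse <- function(obs, pred) sqrt(sum((pred - obs)^2) / length(obs))

# Welch two-sample t statistic, Welch-Satterthwaite df, two-sided p.
oracle_welch <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# OLS through the normal equations (independent of lm/lm.fit QR paths).
oracle_ols_fitted <- function(X, y) {
  A <- cbind(1, X)
  drop(A %*% solve(crossprod(A), crossprod(A, y)))
}

# Random band table with all five bands strictly positive.
random_bands <- function(n, seed = 1, lo = 0.01, hi = 0.99) {
  set.seed(seed)
  data.frame(blue = runif(n, lo, hi), green = runif(n, lo, hi),
             red = runif(n, lo, hi), red_edge = runif(n, lo, hi),
             nir = runif(n, lo, hi))
}

# Feature table shaped like a vi_table: a handful of named index columns is
# enough for the selection primitives, which only require known names.
named_features <- function(...) {
  cols <- list(...)
  stopifnot(all(names(cols) %in% vi_names()))
  data.frame(cols, check.names = FALSE)
}
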