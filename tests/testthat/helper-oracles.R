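# Independent oracles and tiny fixture builders used across the suite.

# Random correlation matrix via a low-rank factor structure (always PSD,
# unit diagonal).
random_corr <- function(R, k = 2, seed = 1) {
  set.seed(seed)
  B <- matrix(rnorm(R * k, sd = 0.5), R, k)
  S <- tcrossprod(B) + diag(runif(R, 0.3, 1))
  stats::cov2cor(S)
}

# Brute-force pairwise Pearson correlation from first principles.
oracle_pairwise_cor <- function(x) {
  R <- ncol(x)
  out <- diag(1, R)
  for (i in seq_len(R - 1)) {
    for (j in (i + 1):R) {
      xi <- x[, i] - mean(x[, i]); xj <- x[, j] - mean(x[, j])
      out[i, j] <- out[j, i] <- sum(xi * xj) / sqrt(sum(xi^2) * sum(xj^2))
    }
  }
  out
}

# OLS residuals through the normal equations (independent of qr-based path).
oracle_ols_residuals <- function(y, X) {
  beta <- solve(t(X) %*% X, t(X) %*% y)
  y - X %*% beta
}

# Benjamini-Hochberg step-up, written from the sorted-p definition.
oracle_bh <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  thresh <- alpha * seq_len(m) / m
  k <- suppressWarnings(max(which(ps <= thresh)))
  rej <- logical(m)
  if (is.finite(k)) rej[o[seq_len(k)]] <- TRUE
  rej
}
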