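# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Column-standardize a matrix (mean 0, sd 1); sd uses the usual n-1 denominator.
.standardize_cols <- function(x) {
  x <- as.matrix(x)
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  if (any(sdv == 0)) {
    .stopf("cannot standardize: column(s) %s have zero variance",
           paste(which(sdv == 0), collapse = ", "))
  }
  sweep(sweep(x, 2, mu, "-"), 2, sdv, "/")
}

# Standardize a vector to mean 0, sd 1.
.standardize_vec <- function(x) {
  s <- stats::sd(x)
  if (s == 0) .stopf("cannot standardize a constant vector")
  (x - mean(x)) / s
}

# Derive a substream seed from a base seed and fixed stream offsets, keeping the
# result inside the 32-bit integer range. Changing later stream indices never
# affects earlier streams because each stream re-seeds independently.
.substream_seed <- function(seed, ...) {
  offs <- c(...)
  s <- (as.numeric(seed) + sum(offs * 9973)) %% 2147483647
  as.integer(s)
}

.is_square_matrix <- function(x) is.matrix(x) && nrow(x) == ncol(x)

.check_symmetric <- function(m, tol = 1e-8, what = "matrix") {
  d <- max(abs(m - t(m)))
  if (d > tol) {
    .stopf("%s is not symmetric (max |m - t(m)| = %.3g exceeds %.1g)", what, d, tol)
  }
  invisible(TRUE)
}
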