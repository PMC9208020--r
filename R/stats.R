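# Inference utilities: Fisher-z transforms, FC-pattern similarity, paired
# similarity comparisons with FDR, the dependent (overlapping) correlation
# comparison, and the weighted-z meta-analysis across samples.

#' Fisher z transform and its inverse
#'
#' `fisher_z` is `atanh(r)` (variance-stabilizing for correlations);
#' `fisher_r` is `tanh(z)`.
#'
#' @param r,z Numeric vectors.
#' @return Transformed numeric vector.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) > 1, na.rm = TRUE)) .stopf("correlations must lie in [-1, 1]")
  atanh(r)
}

#' @rdname fisher_z
#' @export
fisher_r <- function(z) tanh(z)

#' FC pattern similarity
#'
#' Pearson correlation of two connectivity patterns over their vectorized
#' upper-triangle edges — the scalar similarity used to ask how well one FC
#' estimate generalizes to another state's FC.
#'
#' @param fc_a,fc_b Square matrices with the same region count.
#' @return Scalar Pearson r.
#' @export
fc_similarity <- function(fc_a, fc_b) {
  va <- vectorize_edges(fc_a)
  vb <- vectorize_edges(fc_b)
  if (length(va) != length(vb)) .stopf("FC matrices have different region counts")
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
    .stopf("zero-variance edge vector: similarity undefined")
  }
  stats::cor(va, vb)
}

#' Compare two similarity profiles across subjects
#'
#' For each comparison (e.g. each held-out state), a paired t test of the
#' Fisher-z transformed per-subject similarities of model A vs model B, with
#' Benjamini–Hochberg FDR correction across comparisons.
#'
#' @param sim_a,sim_b Subjects x comparisons matrices of similarity r values
#'   (vectors are treated as one comparison).
#' @param alpha FDR level.
#' @param tails `"two"` (default) or `"one"` (alternative: A > B).
#' @return Data frame per comparison: mean z difference, `t`, `p`, `p_fdr`,
#'   `significant`.
#' @export
compare_similarity <- function(sim_a, sim_b, alpha = 0.05, tails = c("two", "one")) {
  tails <- match.arg(tails)
  sim_a <- as.matrix(sim_a); sim_b <- as.matrix(sim_b)
  if (!all(dim(sim_a) == dim(sim_b))) .stopf("similarity matrices differ in shape")
  if (nrow(sim_a) < 3L) .stopf("need >= 3 subjects, have %d", nrow(sim_a))
  K <- ncol(sim_a)
  dz <- tval <- pval <- rep(NA_real_, K)
  for (k in seq_len(K)) {
    d <- fisher_z(sim_a[, k]) - fisher_z(sim_b[, k])
    dz[k] <- mean(d)
    if (stats::sd(d) == 0) {
      tval[k] <- 0; pval[k] <- 1
    } else {
      tt <- stats::t.test(d)
      tval[k] <- unname(tt$statistic)
      pval[k] <- if (tails == "two") tt$p.value else
        stats::pt(unname(tt$statistic), df = length(d) - 1, lower.tail = FALSE)
    }
  }
  p_fdr <- stats::p.adjust(pval, method = "BH")
  nm <- colnames(sim_a) %||% paste0("comparison", seq_len(K))
  data.frame(comparison = nm, mean_z_diff = dz, t = tval, p = pval,
             p_fdr = p_fdr, significant = p_fdr <= alpha, row.names = NULL)
}

#' Test the difference between two dependent overlapping correlations
#'
#' Compares `cor(x, y1) = r1` against `cor(x, y2) = r2` when both share the
#' variable x, accounting for the dependence through `r12 = cor(y1, y2)`. The
#' default is the back-transformed-average Fisher-z variant (Hittner, May &
#' Silver): the z statistic is `(z1 - z2) * sqrt((n - 3) / (2 - 2c))`, where c
#' is the correlation between the two dependent z-transformed coefficients
#' evaluated at the back-transformed average of r1 and r2. `method =
#' "steiger"` uses the plain average of r1 and r2 instead.
#'
#' @param r1,r2 The two correlations sharing a variable.
#' @param r12 Correlation between the two non-shared variables.
#' @param n Sample size (> 3).
#' @param method `"hittner"` (default) or `"steiger"`.
#' @param tails `"two"` (default) or `"one"` (alternative: r1 > r2).
#' @return List with `z` (signed) and `p`.
#' @export
dependent_correlation_test <- function(r1, r2, r12, n,
                                       method = c("hittner", "steiger"),
                                       tails = c("two", "one")) {
  method <- match.arg(method)
  tails <- match.arg(tails)
  for (r in c(r1, r2, r12)) {
    if (!is.finite(r) || abs(r) >= 1) .stopf("correlations must lie strictly in (-1, 1)")
  }
  if (n <= 3) .stopf("n must exceed 3, got %s", n)
  z1 <- atanh(r1); z2 <- atanh(r2)
  rbar <- if (method == "hittner") tanh((z1 + z2) / 2) else (r1 + r2) / 2
  c_num <- r12 * (1 - 2 * rbar^2) - 0.5 * rbar^2 * (1 - 2 * rbar^2 - r12^2)
  c_val <- c_num / (1 - rbar^2)^2
  z <- (z1 - z2) * sqrt((n - 3) / (2 - 2 * c_val))
  p <- if (tails == "two") 2 * stats::pnorm(-abs(z)) else stats::pnorm(z, lower.tail = FALSE)
  list(z = z, p = min(p, 1))
}

#' Weighted-z meta-analysis of correlations
#'
#' Fisher-z transforms each sample's correlation and pools them with weights
#' equal to the sample sizes: `pooled_z = sum(w * z) / sum(w)`. Significance
#' is assessed by a chi-square test of the pooled z against zero with variance
#' `1 / sum(w)`: `chi_square = pooled_z^2 * sum(w)` on 1 df.
#'
#' @param r_values Per-sample correlations, |r| < 1.
#' @param sample_sizes Per-sample sizes (>= 4), used as weights.
#' @return Object of class `meta_z`: `pooled_z`, `pooled_r`, `weights`,
#'   `per_sample_z`, `chi_square`, `df`, `p`.
#' @export
meta_z <- function(r_values, sample_sizes) {
  if (length(r_values) != length(sample_sizes)) {
    .stopf("r_values and sample_sizes differ in length")
  }
  if (any(abs(r_values) >= 1)) .stopf("|r| must be < 1 for the z transform")
  if (any(sample_sizes < 4)) .stopf("sample sizes must be >= 4")
  z <- atanh(r_values)
  w <- as.numeric(sample_sizes)
  pooled <- sum(w * z) / sum(w)
  chisq <- pooled^2 * sum(w)
  structure(list(pooled_z = pooled, pooled_r = tanh(pooled), weights = w,
                 per_sample_z = z, chi_square = chisq, df = 1L,
                 p = stats::pchisq(chisq, df = 1, lower.tail = FALSE)),
            class = "meta_z")
}

#' @export
print.meta_z <- function(x, ...) {
  cat(sprintf("Weighted-z meta-analysis over %d sample(s)\n", length(x$weights)))
  cat(sprintf("  pooled z = %.4f (r = %.4f), chi-square(%d) = %.3f, p = %.4g\n",
              x$pooled_z, x$pooled_r, x$df, x$chi_square, x$p))
  invisible(x)
}
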