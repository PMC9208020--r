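# Activity-flow mapping: predict a held-out region's task activation as the
# connectivity-weighted sum of all other regions' activations, evaluate
# predictions per region/condition/globally with estimate-then-average
# pooling, and compare connectivity models by paired tests on Fisher-z
# accuracies with FDR correction.

#' Activity-flow prediction of task activations
#'
#' For every region j and condition c, `pred[j, c] = sum over i != j of
#' act[i, c] * fc[i, j]`. The connectivity diagonal is ignored (a region never
#' predicts itself).
#'
#' @param activations Regions x conditions activation matrix (or the
#'   `activations` element of [simulate_actflow_activations()] output).
#' @param fc Regions x regions connectivity matrix.
#' @return Regions x conditions predicted activation matrix.
#' @export
actflow_predict <- function(activations, fc) {
  a <- as.matrix(activations)
  W <- unclass(as.matrix(fc))
  if (nrow(W) != nrow(a)) {
    .stopf("connectivity (%d regions) does not match activations (%d regions)",
           nrow(W), nrow(a))
  }
  diag(W) <- 0
  out <- t(W) %*% a
  dimnames(out) <- dimnames(a)
  out
}

#' Evaluate activity-flow predictions across subjects
#'
#' Computes prediction accuracy per unit and subject, then pools across
#' subjects by averaging Fisher-z transformed correlations and
#' back-transforming (estimate-then-average). Units are regions (r across
#' conditions), conditions (r across regions), and the global cell-wise r.
#' Zero-variance units yield `NA` (reported, never silently zero).
#'
#' @param pred,actual Lists of regions x conditions matrices, one per subject
#'   (a single matrix is treated as one subject).
#' @return Object of class `actflow_eval`: `per_region_r`, `per_condition_r`,
#'   `global_r` (pooled), plus per-subject z matrices `region_z`
#'   (subjects x regions), `condition_z`, `global_z`, and `n_subjects`.
#' @export
evaluate_predictions <- function(pred, actual) {
  if (is.matrix(pred)) pred <- list(pred)
  if (is.matrix(actual)) actual <- list(actual)
  if (length(pred) != length(actual)) .stopf("subject counts differ")
  n <- length(pred)
  R <- nrow(pred[[1]]); C <- ncol(pred[[1]])
  region_z <- matrix(NA_real_, n, R)
  condition_z <- matrix(NA_real_, n, C)
  global_z <- rep(NA_real_, n)
  n_undefined <- 0L
  safe_cor <- function(x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y)
  }
  for (s in seq_len(n)) {
    p <- as.matrix(pred[[s]]); a <- as.matrix(actual[[s]])
    if (!all(dim(p) == c(R, C)) || !all(dim(a) == c(R, C))) {
      .stopf("subject %d: prediction/actual shapes do not match %d x %d", s, R, C)
    }
    for (j in seq_len(R)) region_z[s, j] <- fisher_z(safe_cor(p[j, ], a[j, ]))
    for (k in seq_len(C)) condition_z[s, k] <- fisher_z(safe_cor(p[, k], a[, k]))
    global_z[s] <- fisher_z(safe_cor(as.vector(p), as.vector(a)))
  }
  n_undefined <- sum(is.na(region_z)) + sum(is.na(condition_z)) + sum(is.na(global_z))
  if (n_undefined > 0) {
    .warnf("%d undefined correlation(s) (zero-variance unit) reported as NA",
           n_undefined)
  }
  pool <- function(z) fisher_r(colMeans(z, na.rm = TRUE))
  structure(list(per_region_r = pool(region_z),
                 per_condition_r = pool(condition_z),
                 global_r = fisher_r(mean(global_z, na.rm = TRUE)),
                 region_z = region_z, condition_z = condition_z,
                 global_z = global_z, n_subjects = n),
            class = "actflow_eval")
}

#' @export
print.actflow_eval <- function(x, ...) {
  cat(sprintf("Activity-flow evaluation over %d subject(s)\n", x$n_subjects))
  cat(sprintf("  global r = %.3f\n", x$global_r))
  cat(sprintf("  per-region r:    mean %.3f (range %.3f to %.3f)\n",
              mean(x$per_region_r, na.rm = TRUE),
              min(x$per_region_r, na.rm = TRUE), max(x$per_region_r, na.rm = TRUE)))
  cat(sprintf("  per-condition r: mean %.3f (range %.3f to %.3f)\n",
              mean(x$per_condition_r, na.rm = TRUE),
              min(x$per_condition_r, na.rm = TRUE), max(x$per_condition_r, na.rm = TRUE)))
  invisible(x)
}

#' Compare two prediction models per unit
#'
#' Paired t test, per unit (region or condition), of the difference in
#' Fisher-z prediction accuracies across subjects, with Benjamini–Hochberg FDR
#' correction across units. Subjects with an undefined accuracy for a unit are
#' dropped pairwise for that unit (counts logged).
#'
#' @param eval_a,eval_b `actflow_eval` objects over the same subjects.
#' @param unit `"region"` or `"condition"`.
#' @param alpha FDR level (default 0.05).
#' @param tails `"two"` (default) or `"one"` (alternative: A > B).
#' @return Data frame per unit: mean z difference (A - B), `t`, `p`, `p_fdr`,
#'   and `favors` (`"A"`, `"B"`, or `""`), with attributes `pct_favor_a`,
#'   `pct_favor_b`.
#' @export
compare_prediction_models <- function(eval_a, eval_b, unit = c("region", "condition"),
                                      alpha = 0.05, tails = c("two", "one")) {
  stopifnot(inherits(eval_a, "actflow_eval"), inherits(eval_b, "actflow_eval"))
  unit <- match.arg(unit)
  tails <- match.arg(tails)
  za <- if (unit == "region") eval_a$region_z else eval_a$condition_z
  zb <- if (unit == "region") eval_b$region_z else eval_b$condition_z
  if (!all(dim(za) == dim(zb))) .stopf("evaluations have different shapes")
  if (nrow(za) < 3L) .stopf("need >= 3 subjects for the paired test, have %d", nrow(za))
  U <- ncol(za)
  tval <- pval <- dz <- rep(NA_real_, U)
  dropped <- 0L
  for (u in seq_len(U)) {
    d <- za[, u] - zb[, u]
    ok <- is.finite(d)
    dropped <- dropped + sum(!ok)
    d <- d[ok]
    if (length(d) < 3L || stats::sd(d) == 0) {
      dz[u] <- if (length(d)) mean(d) else NA_real_
      tval[u] <- 0
      pval[u] <- 1
      next
    }
    tt <- stats::t.test(d)
    dz[u] <- mean(d)
    tval[u] <- unname(tt$statistic)
    pval[u] <- if (tails == "two") tt$p.value else
      stats::pt(unname(tt$statistic), df = length(d) - 1, lower.tail = FALSE)
  }
  if (dropped > 0) .warnf("%d undefined subject-unit accuracies dropped pairwise", dropped)
  p_fdr <- stats::p.adjust(pval, method = "BH")
  favors <- ifelse(p_fdr <= alpha & dz > 0, "A",
                   ifelse(p_fdr <= alpha & dz < 0, "B", ""))
  out <- data.frame(unit = seq_len(U), mean_z_diff = dz, t = tval,
                    p = pval, p_fdr = p_fdr, favors = favors)
  attr(out, "pct_favor_a") <- 100 * mean(favors == "A")
  attr(out, "pct_favor_b") <- 100 * mean(favors == "B")
  out
}
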