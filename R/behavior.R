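# Behaviour: psychometric g via a single-factor model over cognitive
# measures, cross-sample ridge prediction of g from FC edges, and evaluation
# (r, R-squared, dependent-correlation comparison, meta-analytic pooling).

# Default measure polarity for an 11-measure cognitive battery: reaction-time
# measures are flipped so that higher always means better before fitting.
#' Default cognitive measure polarity configuration
#'
#' One row per measure of the standard 11-measure battery (NIH Toolbox + Penn
#' CNB derived): measure name and direction (+1 higher-is-better, -1 for
#' reaction-time-type measures that are flipped before the g model).
#'
#' @return Data frame with columns `measure` and `direction`.
#' @export
default_measure_config <- function() {
  data.frame(
    measure = c("PicSeq", "CardSort", "Flanker", "PMAT24_CR", "ReadEng",
                "PicVocab", "ProcSpeed", "VSPLOT_TC", "IWRD_TOT", "IWRD_RTC",
                "ListSort"),
    direction = c(1, 1, 1, 1, 1, 1, 1, 1, 1, -1, 1)
  )
}

#' Estimate psychometric g from a battery of cognitive measures
#'
#' Fits a unitary (single-factor) model to the measures and returns
#' regression-method factor scores as the manifest g variable. Measures with
#' negative polarity (e.g. reaction times) are sign-flipped first so all load
#' positively. Colinear (duplicated) measures are refused: the indicator
#' correlation matrix must be invertible for regression scores.
#'
#' @param behavior Subjects x measures numeric matrix (>= 3 measures, more
#'   subjects than measures), no missing values.
#' @param directions Optional +1/-1 vector per measure (default all +1, or
#'   matched from [default_measure_config()] by column name).
#' @param method Factor extraction passed to [fit_single_factor()].
#' @return Object of class `g_scores`: `scores` (standardized), `loadings`,
#'   `solution`.
#' @export
fit_g_scores <- function(behavior, directions = NULL, method = "minres") {
  behavior <- as.matrix(behavior)
  if (anyNA(behavior)) .stopf("behavior matrix contains missing values")
  if (ncol(behavior) < 3L) .stopf("need >= 3 measures, have %d", ncol(behavior))
  if (nrow(behavior) <= ncol(behavior)) {
    .stopf("need more subjects (%d) than measures (%d)", nrow(behavior), ncol(behavior))
  }
  if (is.null(directions)) {
    cfg <- default_measure_config()
    directions <- rep(1, ncol(behavior))
    if (!is.null(colnames(behavior))) {
      hit <- match(colnames(behavior), cfg$measure)
      directions[!is.na(hit)] <- cfg$direction[hit[!is.na(hit)]]
    }
  }
  directions <- rep_len(directions, ncol(behavior))
  x <- sweep(behavior, 2, directions, "*")
  R <- stats::cor(x)
  off <- abs(R[upper.tri(R)])
  if (any(off > 1 - 1e-10)) {
    pair <- which(abs(R) > 1 - 1e-10 & upper.tri(R), arr.ind = TRUE)[1, ]
    .stopf("measures %d and %d are colinear (|r| = 1): g model refused",
           pair[1], pair[2])
  }
  fit <- fit_single_factor(x, method = method)
  structure(list(scores = regression_scores(fit, x),
                 loadings = fit$loadings,
                 solution = fit),
            class = "g_scores")
}

#' @export
print.g_scores <- function(x, ...) {
  cat(sprintf("Psychometric g: %d subjects, %d measures, mean loading %.3f\n",
              length(x$scores), length(x$loadings), mean(x$loadings)))
  invisible(x)
}

#' Cross-sample ridge prediction of an outcome from FC edges
#'
#' Trains a ridge regression on one split and predicts the other, in both
#' directions, so no subject's prediction ever uses a model that saw their
#' data. Features are standardized with the *training* split's statistics
#' only, and the penalty is chosen by k-fold cross-validation inside the
#' training split. Non-circularity requires that the outcome values were also
#' estimated within each split separately (e.g. g factor models per split) —
#' the caller's responsibility, as only the training split's outcomes are read
#' when predicting the other split.
#'
#' @param features Subjects x edges numeric matrix.
#' @param outcome Numeric outcome per subject (e.g. g scores, estimated
#'   per split).
#' @param split_labels Factor/character with exactly two levels partitioning
#'   the subjects (>= 20 per split).
#' @param penalty_grid Ridge penalty grid (default `10^seq(-3, 5, by = 0.5)`).
#' @param nfolds CV folds within the training split (default 5).
#' @param seed Seed for the CV fold assignment.
#' @return Numeric vector of predictions aligned to subjects, with attribute
#'   `chosen_penalty` (one per direction).
#' @export
cross_sample_ridge_predict <- function(features, outcome, split_labels,
                                       penalty_grid = 10^seq(-3, 5, by = 0.5),
                                       nfolds = 5, seed = 1) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (length(outcome) != n || length(split_labels) != n) {
    .stopf("features, outcome and split_labels must agree in length")
  }
  split_labels <- as.character(split_labels)
  lv <- unique(split_labels)
  if (length(lv) != 2L) .stopf("split_labels must have exactly two levels, found %d",
                               length(lv))
  n1 <- sum(split_labels == lv[1]); n2 <- sum(split_labels == lv[2])
  if (min(n1, n2) < 20L) .stopf("each split needs >= 20 subjects (have %d and %d)",
                                n1, n2)
  preds <- rep(NA_real_, n)
  chosen <- stats::setNames(numeric(2), lv)
  # glmnet's lambda is the penalty per observation; divide the grid by the
  # training n so the grid is on the summed-penalty scale.
  lam_sorted <- sort(unique(penalty_grid), decreasing = TRUE)
  for (k in 1:2) {
    train <- split_labels == lv[k]
    test <- !train
    Xtr <- features[train, , drop = FALSE]
    mu <- colMeans(Xtr)
    sdv <- apply(Xtr, 2, stats::sd)
    sdv[sdv == 0] <- 1
    Ztr <- sweep(sweep(Xtr, 2, mu, "-"), 2, sdv, "/")
    Zte <- sweep(sweep(features[test, , drop = FALSE], 2, mu, "-"), 2, sdv, "/")
    ytr <- outcome[train]
    set.seed(.substream_seed(seed, 8, k))
    folds <- sample(rep_len(seq_len(nfolds), length(ytr)))
    cvfit <- glmnet::cv.glmnet(Ztr, ytr, alpha = 0,
                               lambda = lam_sorted / length(ytr),
                               foldid = folds, standardize = FALSE)
    preds[test] <- drop(stats::predict(cvfit, newx = Zte, s = "lambda.min"))
    chosen[lv[k]] <- cvfit$lambda.min * length(ytr)
  }
  attr(preds, "chosen_penalty") <- chosen
  preds
}

#' Evaluate behavioural predictions
#'
#' Pearson r and R-squared (= r^2) between predicted and actual outcome, per
#' split and pooled. When a competing prediction set is supplied, the
#' difference in predictive correlations is tested per split with the
#' dependent-correlation comparison (the two predictions share the actual
#' outcome) and pooled across splits with the weighted-z meta-analysis.
#'
#' @param predicted,actual Aligned numeric vectors.
#' @param split_labels Two-level split labels (optional; one split if `NULL`).
#' @param predicted_alt Optional competing predictions (e.g. from another
#'   connectivity model) for the delta-r comparison.
#' @param tails Tails for the dependent-correlation test.
#' @return Object of class `behavior_eval`: data frame `by_split` (r, r_squared,
#'   n per split and overall), and if `predicted_alt` is given `delta`
#'   (per-split z, p) and `meta` (a [meta_z] of the per-split differences...
#'   pooled delta z and its chi-square p).
#' @export
evaluate_behavior_prediction <- function(predicted, actual, split_labels = NULL,
                                         predicted_alt = NULL,
                                         tails = c("two", "one")) {
  tails <- match.arg(tails)
  if (length(predicted) != length(actual)) .stopf("length mismatch")
  split_labels <- split_labels %||% rep("all", length(actual))
  split_labels <- as.character(split_labels)
  groups <- c(as.list(unique(split_labels)), list(unique(split_labels)))
  nm <- c(unique(split_labels), "overall")
  rows <- lapply(seq_along(groups), function(i) {
    sel <- split_labels %in% groups[[i]]
    r <- stats::cor(predicted[sel], actual[sel])
    data.frame(split = nm[i], n = sum(sel), r = r, r_squared = r^2)
  })
  by_split <- do.call(rbind, rows)
  out <- list(by_split = by_split)
  if (!is.null(predicted_alt)) {
    if (length(predicted_alt) != length(actual)) .stopf("length mismatch (alt)")
    lv <- unique(split_labels)
    delta <- lapply(lv, function(g) {
      sel <- split_labels == g
      r1 <- stats::cor(predicted[sel], actual[sel])
      r2 <- stats::cor(predicted_alt[sel], actual[sel])
      r12 <- stats::cor(predicted[sel], predicted_alt[sel])
      tst <- dependent_correlation_test(r1, r2, r12, sum(sel), tails = tails)
      data.frame(split = g, n = sum(sel), r_main = r1, r_alt = r2,
                 delta_r = r1 - r2, delta_z = atanh(r1) - atanh(r2),
                 z = tst$z, p = tst$p)
    })
    out$delta <- do.call(rbind, delta)
    # pool the per-split z differences with sample-size weights
    w <- out$delta$n
    pooled <- sum(w * out$delta$delta_z) / sum(w)
    chisq <- pooled^2 * sum(w)
    out$meta <- structure(list(pooled_z = pooled, pooled_r = tanh(pooled),
                               weights = w, per_sample_z = out$delta$delta_z,
                               chi_square = chisq, df = 1L,
                               p = stats::pchisq(chisq, 1, lower.tail = FALSE)),
                          class = "meta_z")
  }
  class(out) <- "behavior_eval"
  out
}

#' @export
print.behavior_eval <- function(x, ...) {
  cat("Behavioural prediction evaluation\n")
  tab <- x$by_split
  tab$r <- round(tab$r, 3); tab$r_squared <- round(tab$r_squared, 3)
  print(tab, row.names = FALSE)
  if (!is.null(x$delta)) {
    cat("Delta-r (main vs alternative predictions):\n")
    d <- x$delta
    d[, -1] <- round(d[, -1], 4)
    print(d, row.names = FALSE)
    cat(sprintf("Pooled delta z = %.4f, p = %.4g\n", x$meta$pooled_z, x$meta$p))
  }
  invisible(x)
}
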