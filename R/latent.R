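# Latent FC: an independent single-factor model per edge across brain states,
# with a leave-one-state-out variant, the average-FC baseline, and loading
# summaries.

#' Estimate latent functional connectivity
#'
#' Fits, independently for every network edge, a single-factor model across
#' brain states: each state's FC value at that edge is an indicator of the
#' edge's latent (state-general, "intrinsic") connectivity. Subject-level
#' latent FC is the regression-method factor score per edge; the group matrix
#' is the mean score per edge folded back into a regions x regions matrix.
#'
#' Setting `exclude_state` removes one state *before* any fitting, giving the
#' leave-one-state-out (LOSO) estimate used for non-circular prediction of the
#' held-out state: nothing in the returned object depends on the excluded
#' state's values.
#'
#' Because standardized factor scores average to zero across subjects by
#' construction, the group matrix is computed in the raw FC metric: each
#' edge's score weights are normalized to sum to one and applied to the raw
#' (unstandardized) indicators, then averaged over subjects. Under equal
#' weights this reduces exactly to the group average-FC matrix; unequal
#' weights tilt it toward the states that load more strongly on the latent
#' edge.
#'
#' Edges whose fit fails (or whose indicators have zero variance) fall back to
#' the restricted equal-loading model — i.e. the across-state average — and are
#' flagged; the count is reported by `print()`.
#'
#' @param stack An [fc_stack] (subjects x states x edges); >= 3 included
#'   states and >= 10 subjects.
#' @param exclude_state Optional state label to hold out.
#' @param method Factor extraction, `"minres"` (default) or `"ml"`.
#' @param heywood_floor Passed to [fit_single_factor()].
#' @return An object of class `latent_fc` with elements `scores` (subjects x
#'   edges standardized factor scores), `group_matrix` (regions x regions mean
#'   score, zero diagonal), `loadings` (included-states x edges),
#'   `uniquenesses`, `flagged` (logical per edge: fallback used), `heywood`
#'   (logical per edge), `included_states`, `excluded_state`, `method`,
#'   `edge_index`, `n_regions`, `subject_ids`.
#' @examples
#' sim <- simulate_fc_stack(n_subjects = 40, n_regions = 5, n_states = 4,
#'                          loading_spec = 0.7, seed = 1)
#' fit <- latent_fc(sim$stack)
#' fit
#' @export
latent_fc <- function(stack, exclude_state = NULL, method = c("minres", "ml"),
                      heywood_floor = 0.001) {
  stopifnot(inherits(stack, "fc_stack"))
  method <- match.arg(method)
  states <- stack$state_labels
  if (!is.null(exclude_state)) {
    if (!exclude_state %in% states) {
      .stopf("exclude_state '%s' is not a state of the stack (%s)",
             exclude_state, paste(states, collapse = ", "))
    }
    keep <- states != exclude_state
  } else {
    keep <- rep(TRUE, length(states))
  }
  inc <- states[keep]
  if (length(inc) < 3L) {
    .stopf("need >= 3 included states for the factor model, have %d", length(inc))
  }
  N <- dim(stack$values)[1]
  if (N < 10L) .stopf("need >= 10 subjects, have %d", N)
  E <- dim(stack$values)[3]

  scores <- matrix(NA_real_, N, E)
  raw_scores <- matrix(NA_real_, N, E)
  loadings <- matrix(NA_real_, length(inc), E, dimnames = list(inc, NULL))
  uniq <- matrix(NA_real_, length(inc), E, dimnames = list(inc, NULL))
  flagged <- logical(E)
  heywood <- logical(E)

  for (e in seq_len(E)) {
    ind <- stack$values[, keep, e, drop = TRUE]
    colnames(ind) <- inc
    sdv <- apply(ind, 2, stats::sd)
    fit <- NULL
    if (all(sdv > 0)) {
      fit <- tryCatch(
        suppressWarnings(fit_single_factor(ind, method = method,
                                           heywood_floor = heywood_floor)),
        error = function(err) NULL)
    }
    if (is.null(fit) || !fit$converged) {
      flagged[e] <- TRUE
      rs <- restricted_average_solution(ind)
      sc <- rs$scores
      scores[, e] <- if (stats::sd(sc) > 0) .standardize_vec(sc) else sc - mean(sc)
      raw_scores[, e] <- sc
      loadings[, e] <- 1
      uniq[, e] <- 0
    } else {
      scores[, e] <- regression_scores(fit, ind)
      # raw-metric score: normalized score weights on the raw indicators
      w <- fit$score_weights
      w <- if (sum(w) > 1e-8) w / sum(w) else rep(1 / length(w), length(w))
      raw_scores[, e] <- drop(ind %*% w)
      loadings[, e] <- fit$loadings
      uniq[, e] <- fit$uniquenesses
      heywood[e] <- fit$heywood
    }
  }
  if (any(flagged)) {
    message(sprintf("latent_fc: %d of %d edges fell back to the restricted (average) model",
                    sum(flagged), E))
  }
  group_matrix <- devectorize_edges(colMeans(raw_scores), stack$n_regions,
                                    diag_value = 0)

  structure(list(scores = scores, group_matrix = group_matrix,
                 loadings = loadings, uniquenesses = uniq,
                 flagged = flagged, heywood = heywood,
                 included_states = inc,
                 excluded_state = exclude_state,
                 method = method,
                 edge_index = stack$edge_index,
                 n_regions = stack$n_regions,
                 subject_ids = stack$subject_ids,
                 state_labels = states),
            class = "latent_fc")
}

#' Average FC baseline
#'
#' Per subject and edge, the arithmetic mean FC across states — identical to
#' the restricted equal-loading factor solution applied edgewise.
#'
#' @param stack An [fc_stack].
#' @param exclude_state Optional state label to hold out before averaging.
#' @return Subjects x edges numeric matrix.
#' @export
average_fc <- function(stack, exclude_state = NULL) {
  stopifnot(inherits(stack, "fc_stack"))
  keep <- rep(TRUE, length(stack$state_labels))
  if (!is.null(exclude_state)) {
    if (!exclude_state %in% stack$state_labels) {
      .stopf("exclude_state '%s' is not a state of the stack", exclude_state)
    }
    keep <- stack$state_labels != exclude_state
  }
  if (!any(keep)) .stopf("no states left to average")
  apply(stack$values[, keep, , drop = FALSE], c(1, 3), mean)
}

#' Summarize factor loadings per state
#'
#' For each included state, the percentage of edges with nonnegative loadings,
#' the percentage with loadings at or above `threshold` (inclusive), and the
#' mean loading. This is the positive-manifold summary: under a common latent
#' architecture nearly all loadings are positive and most are sizeable.
#'
#' @param latent A `latent_fc` fit.
#' @param threshold Loading threshold (default 0.4), compared inclusively.
#' @return Data frame with one row per state: `state`, `pct_nonnegative`,
#'   `pct_at_threshold`, `mean_loading`.
#' @export
summarize_loadings <- function(latent, threshold = 0.4) {
  stopifnot(inherits(latent, "latent_fc"))
  L <- latent$loadings
  data.frame(state = rownames(L),
             pct_nonnegative = 100 * rowMeans(L >= 0),
             pct_at_threshold = 100 * rowMeans(L >= threshold),
             mean_loading = rowMeans(L),
             row.names = NULL)
}

#' Subject-level latent FC matrix
#'
#' Folds one subject's edge scores back into a regions x regions matrix
#' (zero diagonal: factor scores have no self-connection scale).
#'
#' @param latent A `latent_fc` fit.
#' @param subject Subject index or id.
#' @return Square numeric matrix.
#' @export
latent_fc_matrix <- function(latent, subject) {
  stopifnot(inherits(latent, "latent_fc"))
  if (is.character(subject)) subject <- match(subject, latent$subject_ids)
  if (is.na(subject) || subject < 1 || subject > nrow(latent$scores)) {
    .stopf("unknown subject")
  }
  devectorize_edges(latent$scores[subject, ], latent$n_regions, diag_value = 0)
}

#' @export
print.latent_fc <- function(x, ...) {
  cat(sprintf("Latent FC fit (%s): %d subjects, %d edges (%d regions), %d states\n",
              x$method, nrow(x$scores), ncol(x$scores), x$n_regions,
              length(x$included_states)))
  if (!is.null(x$excluded_state)) {
    cat(sprintf("  leave-one-state-out: '%s' excluded from fitting\n", x$excluded_state))
  }
  cat(sprintf("  mean loading %.3f; %d edge(s) fell back to the average model; %d Heywood\n",
              mean(x$loadings), sum(x$flagged), sum(x$heywood)))
  invisible(x)
}

#' @export
summary.latent_fc <- function(object, threshold = 0.4, ...) {
  out <- list(loading_table = summarize_loadings(object, threshold = threshold),
              threshold = threshold,
              n_subjects = nrow(object$scores),
              n_edges = ncol(object$scores),
              n_regions = object$n_regions,
              excluded_state = object$excluded_state,
              n_flagged = sum(object$flagged),
              n_heywood = sum(object$heywood),
              method = object$method)
  class(out) <- "summary.latent_fc"
  out
}

#' @export
print.summary.latent_fc <- function(x, ...) {
  cat(sprintf("Latent FC (%s): %d subjects x %d edges (%d regions)\n",
              x$method, x$n_subjects, x$n_edges, x$n_regions))
  if (!is.null(x$excluded_state)) cat(sprintf("  excluded state: %s\n", x$excluded_state))
  cat(sprintf("  %d flagged edge(s), %d Heywood case(s)\n", x$n_flagged, x$n_heywood))
  cat(sprintf("Per-state loadings (threshold %.2f, inclusive):\n", x$threshold))
  tab <- x$loading_table
  tab[, -1] <- round(tab[, -1], 2)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
coef.latent_fc <- function(object, ...) object$loadings

#' @describeIn latent_fc activity-flow prediction of task activations from the
#'   fitted connectivity (see [actflow_predict()]); `connectivity` chooses the
#'   group matrix or one subject's score matrix.
#' @param object A `latent_fc` fit.
#' @param activations Regions x conditions activation matrix.
#' @param connectivity `"group"` or a subject index/id.
#' @param ... Unused.
#' @export
predict.latent_fc <- function(object, activations,
                              connectivity = "group", ...) {
  W <- if (identical(connectivity, "group")) object$group_matrix
       else latent_fc_matrix(object, connectivity)
  actflow_predict(activations, W)
}

#' @export
plot.latent_fc <- function(x, main = "Group latent FC (mean factor score)", ...) {
  m <- x$group_matrix
  graphics::image(seq_len(nrow(m)), seq_len(ncol(m)), t(m[nrow(m):1, ]),
                  xlab = "region", ylab = "region", main = main,
                  col = grDevices::hcl.colors(64, "Blue-Red 3"), ...)
  invisible(x)
}

#' @describeIn latent_fc draw new indicator stacks from the fitted per-edge
#'   model: for each edge, `y[i,s] = lambda[s] * score[i] + sqrt(uniq[s]) * noise`.
#' @param nsim Number of stacks to simulate.
#' @param seed Integer seed.
#' @export
simulate.latent_fc <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  N <- nrow(object$scores); E <- ncol(object$scores)
  S <- length(object$included_states)
  out <- vector("list", nsim)
  for (k in seq_len(nsim)) {
    vals <- array(NA_real_, c(N, S, E))
    for (e in seq_len(E)) {
      lam <- object$loadings[, e]
      un <- pmax(object$uniquenesses[, e], 0)
      eta <- object$scores[, e]
      noise <- matrix(stats::rnorm(N * S), N, S)
      vals[, , e] <- outer(eta, lam) + sweep(noise, 2, sqrt(un), "*")
    }
    out[[k]] <- fc_stack(vals, n_regions = object$n_regions,
                         state_labels = object$included_states,
                         subject_ids = object$subject_ids)
  }
  if (nsim == 1L) out[[1]] else out
}

#' @describeIn latent_fc per-edge indicator residuals against the fitted
#'   common part, `y[i,s,e] - lambda[s,e] * score[i,e]`, given the stack the
#'   model was fit to.
#' @param stack The [fc_stack] the model was fit to.
#' @export
residuals.latent_fc <- function(object, stack, ...) {
  stopifnot(inherits(stack, "fc_stack"))
  keep <- stack$state_labels %in% object$included_states
  vals <- stack$values[, keep, , drop = FALSE]
  E <- dim(vals)[3]
  res <- vals
  for (e in seq_len(E)) {
    # residual in the standardized indicator metric
    z <- .standardize_cols(vals[, , e, drop = TRUE])
    res[, , e] <- z - outer(object$scores[, e], object$loadings[, e])
  }
  res
}
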