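# Functional-connectivity estimation: per-state correlation matrices,
# edge vectorization, and TR-budget matching across states.

#' Parcellated BOLD time series container
#'
#' Bundles a timepoints x regions numeric matrix with run/state/subject labels.
#' All preprocessing and FC functions accept either a plain matrix or this
#' container; run labels are required only where per-run operations
#' (concatenation, z-normalization) need them.
#'
#' @param values Numeric matrix, timepoints x regions.
#' @param run Run label per timepoint (length `nrow(values)`), or a single
#'   label recycled to all timepoints.
#' @param state State (task/rest) label.
#' @param subject Subject identifier.
#' @return An object of class `parcellated_ts`.
#' @export
parcellated_ts <- function(values, run = "run1", state = NA_character_,
                           subject = NA_character_) {
  values <- as.matrix(values)
  if (!is.numeric(values)) .stopf("time series values must be numeric")
  if (length(run) == 1L) run <- rep(run, nrow(values))
  if (length(run) != nrow(values)) {
    .stopf("run labels (%d) do not match timepoints (%d)", length(run), nrow(values))
  }
  structure(list(values = values, run = as.character(run),
                 state = state, subject = subject),
            class = "parcellated_ts")
}

#' @export
print.parcellated_ts <- function(x, ...) {
  cat(sprintf("Parcellated time series: %d timepoints x %d regions (%d run%s)\n",
              nrow(x$values), ncol(x$values), length(unique(x$run)),
              if (length(unique(x$run)) == 1L) "" else "s"))
  if (!is.na(x$state)) cat("  state:  ", x$state, "\n")
  if (!is.na(x$subject)) cat("  subject:", x$subject, "\n")
  invisible(x)
}

.ts_values <- function(x) {
  if (inherits(x, "parcellated_ts")) x$values else as.matrix(x)
}

#' Functional connectivity matrix container
#'
#' A regions x regions zero-lag Pearson correlation matrix with metadata.
#' Enforces the FC invariants: symmetry, unit diagonal, entries in \[-1, 1\],
#' finiteness.
#'
#' @param values Square numeric correlation matrix.
#' @param state State label the matrix was estimated from.
#' @param subject Subject identifier.
#' @param n_trs_used Number of timepoints that entered the estimate.
#' @return An object of class `fc_matrix` (a matrix with attributes).
#' @export
fc_matrix <- function(values, state = NA_character_, subject = NA_character_,
                      n_trs_used = NA_integer_) {
  values <- as.matrix(values)
  if (!.is_square_matrix(values)) .stopf("FC matrix must be square")
  if (any(!is.finite(values))) .stopf("FC matrix contains non-finite entries")
  .check_symmetric(values, what = "FC matrix")
  values <- (values + t(values)) / 2
  if (max(abs(diag(values) - 1)) > 1e-8) .stopf("FC matrix diagonal must be 1")
  diag(values) <- 1
  if (max(abs(values)) > 1 + 1e-8) .stopf("FC entries must lie in [-1, 1]")
  values[values > 1] <- 1
  values[values < -1] <- -1
  structure(values, class = c("fc_matrix", "matrix"),
            state = state, subject = subject, n_trs_used = n_trs_used)
}

#' @export
print.fc_matrix <- function(x, ...) {
  cat(sprintf("FC matrix: %d regions", nrow(x)))
  st <- attr(x, "state"); nt <- attr(x, "n_trs_used")
  if (!is.na(st)) cat(sprintf(", state '%s'", st))
  if (!is.na(nt)) cat(sprintf(", %d TRs", nt))
  cat("\n")
  print(unclass(x)[seq_len(min(6L, nrow(x))), seq_len(min(6L, ncol(x))), drop = FALSE])
  if (nrow(x) > 6L) cat(sprintf("  ... (%d regions total)\n", nrow(x)))
  invisible(x)
}

#' Compute functional connectivity from (concatenated) runs
#'
#' Estimates zero-lag Pearson correlations between all region pairs. Multiple
#' runs of the same state are concatenated in time (never averaged) before the
#' correlation is taken; an optional TR mask restricts which concatenated
#' timepoints are used (e.g. on-task TRs only, or a TR budget).
#'
#' @param runs A matrix, a `parcellated_ts`, or a list of either (same region
#'   count); list elements are concatenated in order.
#' @param mask Optional logical vector over the concatenated timepoints.
#' @param state,subject Metadata carried onto the result.
#' @return An [fc_matrix] with `n_trs_used` recorded.
#' @export
compute_fc <- function(runs, mask = NULL, state = NA_character_,
                       subject = NA_character_) {
  if (!is.list(runs) || inherits(runs, "parcellated_ts")) runs <- list(runs)
  mats <- lapply(runs, .ts_values)
  rcount <- vapply(mats, ncol, integer(1))
  if (length(unique(rcount)) != 1L) {
    .stopf("runs disagree on region count: %s", paste(unique(rcount), collapse = ", "))
  }
  x <- do.call(rbind, mats)
  if (inherits(runs[[1]], "parcellated_ts") && is.na(state)) state <- runs[[1]]$state
  if (inherits(runs[[1]], "parcellated_ts") && is.na(subject)) subject <- runs[[1]]$subject
  if (!is.null(mask)) {
    mask <- as.logical(mask)
    if (length(mask) != nrow(x)) {
      .stopf("mask length (%d) does not match concatenated timepoints (%d)",
             length(mask), nrow(x))
    }
    x <- x[mask, , drop = FALSE]
  }
  if (nrow(x) < 3L) .stopf("need at least 3 timepoints to estimate FC, got %d", nrow(x))
  sdv <- apply(x, 2, stats::sd)
  if (any(sdv == 0)) {
    .stopf("zero-variance region(s) after masking: %s",
           paste(which(sdv == 0), collapse = ", "))
  }
  fc_matrix(stats::cor(x), state = state, subject = subject, n_trs_used = nrow(x))
}

#' Edge index for a region count
#'
#' Enumerates the upper-triangle region pairs (i < j) in row-major order:
#' (1,2), (1,3), ..., (1,R), (2,3), .... Every module in the package shares
#' this one edge ordering.
#'
#' @param n_regions Number of regions R.
#' @return Integer matrix with columns `i`, `j` and R(R-1)/2 rows.
#' @export
edge_index <- function(n_regions) {
  if (n_regions < 2L) .stopf("need at least 2 regions")
  idx <- t(utils::combn(n_regions, 2L))
  colnames(idx) <- c("i", "j")
  idx
}

#' Vectorize the upper triangle of an FC matrix
#'
#' Extracts off-diagonal edges in the package's row-major upper-triangle order
#' (see [edge_index]); [devectorize_edges] is the exact inverse.
#'
#' @param fc Symmetric square matrix (checked to 1e-8).
#' @return Numeric vector of length R(R-1)/2.
#' @export
vectorize_edges <- function(fc) {
  m <- unclass(as.matrix(fc))
  if (!.is_square_matrix(m)) .stopf("FC matrix must be square")
  .check_symmetric(m, what = "FC matrix")
  # column-major lower triangle of t(m) == row-major upper triangle of m
  tm <- t(m)
  tm[lower.tri(tm)]
}

#' @rdname vectorize_edges
#' @param edges Edge vector as produced by [vectorize_edges].
#' @param n_regions Region count R; `length(edges)` must equal R(R-1)/2.
#' @param diag_value Value placed on the diagonal of the rebuilt matrix.
#' @export
devectorize_edges <- function(edges, n_regions, diag_value = 1) {
  ne <- n_regions * (n_regions - 1) / 2
  if (length(edges) != ne) {
    .stopf("edge vector length %d does not match %d regions (expected %d)",
           length(edges), n_regions, ne)
  }
  m <- matrix(0, n_regions, n_regions)
  tm <- t(m)
  tm[lower.tri(tm)] <- edges
  m <- t(tm)
  m <- m + t(m)
  diag(m) <- diag_value
  m
}

#' FC stack: subjects x states x edges
#'
#' The central container for multi-state connectivity: for each subject and
#' brain state, the vectorized edges of that state's FC matrix. Indicators for
#' the per-edge factor model are slices `values[, , e]`.
#'
#' @param values 3-d numeric array, subjects x states x edges.
#' @param n_regions Region count consistent with the edge dimension.
#' @param state_labels,subject_ids Optional dimension labels.
#' @return An object of class `fc_stack`.
#' @export
fc_stack <- function(values, n_regions, state_labels = NULL, subject_ids = NULL) {
  if (length(dim(values)) != 3L) .stopf("stack values must be a 3-d array")
  ne <- n_regions * (n_regions - 1) / 2
  if (dim(values)[3] != ne) {
    .stopf("edge dimension %d does not match %d regions (expected %d)",
           dim(values)[3], n_regions, ne)
  }
  state_labels <- state_labels %||% paste0("state", seq_len(dim(values)[2]))
  subject_ids <- subject_ids %||% paste0("sub", seq_len(dim(values)[1]))
  if (length(state_labels) != dim(values)[2]) .stopf("state label count mismatch")
  if (length(subject_ids) != dim(values)[1]) .stopf("subject id count mismatch")
  dimnames(values) <- list(subject_ids, state_labels, NULL)
  structure(list(values = values, n_regions = n_regions,
                 edge_index = edge_index(n_regions),
                 state_labels = state_labels, subject_ids = subject_ids),
            class = "fc_stack")
}

#' @export
print.fc_stack <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("FC stack: %d subjects x %d states x %d edges (%d regions)\n",
              d[1], d[2], d[3], x$n_regions))
  cat("  states:", paste(x$state_labels, collapse = ", "), "\n")
  invisible(x)
}

#' Build an FC stack from per-subject, per-state FC matrices
#'
#' @param fc_list Nested list: `fc_list[[subject]][[state]]` is an [fc_matrix]
#'   (or plain symmetric matrix); all must share the region count.
#' @param state_labels,subject_ids Optional labels; defaults taken from names.
#' @return An [fc_stack].
#' @export
stack_fc <- function(fc_list, state_labels = NULL, subject_ids = NULL) {
  ns <- length(fc_list)
  if (ns == 0L) .stopf("empty FC list")
  nst <- length(fc_list[[1]])
  R <- nrow(as.matrix(fc_list[[1]][[1]]))
  ne <- R * (R - 1) / 2
  vals <- array(NA_real_, c(ns, nst, ne))
  for (i in seq_len(ns)) {
    if (length(fc_list[[i]]) != nst) .stopf("subject %d has %d states, expected %d",
                                            i, length(fc_list[[i]]), nst)
    for (s in seq_len(nst)) vals[i, s, ] <- vectorize_edges(fc_list[[i]][[s]])
  }
  state_labels <- state_labels %||% names(fc_list[[1]]) %||% paste0("state", seq_len(nst))
  subject_ids <- subject_ids %||% names(fc_list) %||% paste0("sub", seq_len(ns))
  fc_stack(vals, n_regions = R, state_labels = state_labels, subject_ids = subject_ids)
}

#' Match the TR budget across states
#'
#' Selects, deterministically, the first eligible TRs of each state so that all
#' task states contribute the same number of timepoints and rest contributes
#' the summed task budget. Defaults follow the standard matched design: 264
#' on-task TRs per task (the shortest task is the limiting factor) and
#' 8 x 264 = 2,112 rest TRs.
#'
#' @param masks Named list of logical eligibility vectors, one per state (TRUE
#'   where a TR may be used: on-task TRs for tasks, all retained TRs for rest).
#' @param rest_state Name of the rest state in `masks` (or `NULL` if absent).
#' @param rest_budget,task_budget TR budgets for rest and for each task state.
#' @param sample_seed If non-`NULL`, sample the budget uniformly from eligible
#'   TRs with this seed instead of taking the first N.
#' @return Named list of logical selection masks, each summing to its budget.
#' @export
match_tr_budget <- function(masks, rest_state = "rest", rest_budget = 2112,
                            task_budget = 264, sample_seed = NULL) {
  if (is.null(names(masks)) || any(!nzchar(names(masks)))) {
    .stopf("masks must be a fully named list of eligibility vectors")
  }
  out <- vector("list", length(masks))
  names(out) <- names(masks)
  for (nm in names(masks)) {
    elig <- as.logical(masks[[nm]])
    budget <- if (!is.null(rest_state) && nm == rest_state) rest_budget else task_budget
    avail <- sum(elig)
    if (avail < budget) {
      .stopf("state '%s' has only %d eligible TRs for a budget of %d (short %d)",
             nm, avail, budget, budget - avail)
    }
    sel <- logical(length(elig))
    idx <- which(elig)
    if (is.null(sample_seed)) {
      sel[idx[seq_len(budget)]] <- TRUE
    } else {
      old <- .Random.seed_save()
      set.seed(.substream_seed(sample_seed, match(nm, names(masks))))
      sel[sort(sample(idx, budget))] <- TRUE
      .Random.seed_restore(old)
    }
    out[[nm]] <- sel
  }
  out
}

# Save/restore the RNG state so utility sampling does not disturb user streams.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}
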