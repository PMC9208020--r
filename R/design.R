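# Nuisance and FIR design construction plus residualization/normalization —
# the preprocessing stages applied to parcellated time series before FC
# estimation.
#
# Conventions: TR indices are 0-based; a block covers the half-open interval
# [onset, onset + duration). Derivatives are backward first differences with a
# leading zero (length-preserving); quadratics are computed after derivative
# construction, on the assembled level+derivative block.

#' Task condition block timing
#'
#' @param condition_name Condition label.
#' @param block_onsets 0-based TR indices, strictly increasing.
#' @param block_durations Block lengths in TRs (recycled if scalar).
#' @param run_length_trs Optional run length for bounds validation.
#' @return Object of class `condition_timing`.
#' @export
condition_timing <- function(condition_name, block_onsets, block_durations,
                             run_length_trs = NULL) {
  if (length(block_onsets) == 0L) .stopf("condition '%s' has no blocks", condition_name)
  block_durations <- rep_len(block_durations, length(block_onsets))
  if (any(diff(block_onsets) <= 0)) {
    .stopf("condition '%s': block onsets must be strictly increasing", condition_name)
  }
  if (any(block_durations < 1)) .stopf("condition '%s': block durations must be >= 1 TR",
                                       condition_name)
  ends <- block_onsets + block_durations
  if (any(utils::head(ends, -1) > utils::tail(block_onsets, -1))) {
    .stopf("condition '%s': blocks overlap within the condition", condition_name)
  }
  if (!is.null(run_length_trs) && any(ends > run_length_trs)) {
    .stopf("condition '%s': block extends past run end (%d TRs)",
           condition_name, run_length_trs)
  }
  structure(list(condition_name = condition_name,
                 block_onsets = as.integer(block_onsets),
                 block_durations = as.integer(block_durations)),
            class = "condition_timing")
}

#' Build the 64-column nuisance design
#'
#' Assembles the standard nuisance regression model: the 6 motion parameters,
#' their backward-difference derivatives, and the quadratics of all 12 (24
#' motion regressors), then the 10 anatomical-noise components (5 white
#' matter + 5 ventricle), their derivatives, and the quadratics of all 20
#' (40 physiological regressors) — 64 columns in total.
#'
#' @param motion T x 6 motion parameter matrix.
#' @param wm_components,ventricle_components T x 5 aCompCor component matrices.
#' @return Labeled T x 64 design matrix.
#' @export
build_nuisance_regressors <- function(motion, wm_components, ventricle_components) {
  motion <- as.matrix(motion)
  wm_components <- as.matrix(wm_components)
  ventricle_components <- as.matrix(ventricle_components)
  if (ncol(motion) != 6L) .stopf("motion must have 6 columns, has %d", ncol(motion))
  if (ncol(wm_components) != 5L) .stopf("wm_components must have 5 columns, has %d",
                                        ncol(wm_components))
  if (ncol(ventricle_components) != 5L) {
    .stopf("ventricle_components must have 5 columns, has %d", ncol(ventricle_components))
  }
  Tn <- nrow(motion)
  if (nrow(wm_components) != Tn || nrow(ventricle_components) != Tn) {
    .stopf("row counts differ: motion %d, wm %d, ventricles %d",
           Tn, nrow(wm_components), nrow(ventricle_components))
  }
  deriv <- function(x) rbind(0, diff(x))

  colnames(motion) <- paste0("motion", 1:6)
  mblock <- cbind(motion, `colnames<-`(deriv(motion), paste0("motion_d", 1:6)))
  mblock <- cbind(mblock, `colnames<-`(mblock^2, paste0(colnames(mblock), "_sq")))

  comps <- cbind(`colnames<-`(wm_components, paste0("wm", 1:5)),
                 `colnames<-`(ventricle_components, paste0("vent", 1:5)))
  cblock <- cbind(comps, `colnames<-`(deriv(comps), paste0(colnames(comps), "_d")))
  cblock <- cbind(cblock, `colnames<-`(cblock^2, paste0(colnames(cblock), "_sq")))

  out <- cbind(mblock, cblock)
  stopifnot(ncol(out) == 64L)
  out
}

#' Build a finite impulse response (FIR) task design
#'
#' One indicator column per within-block timepoint offset per condition,
#' pooled across that condition's blocks, plus `extra_lags` post-offset lag
#' columns per condition (capturing the hemodynamic tail after block offset).
#' A condition contributes `max(block duration) + extra_lags` columns. Lag
#' entries falling past the run end are simply absent (their rows do not
#' exist); the columns themselves are retained.
#'
#' @param timings List of [condition_timing] objects (or a single one).
#' @param run_length_trs Run length in TRs.
#' @param extra_lags Post-offset lag columns per condition (default 25).
#' @return Labeled T x (sum per-condition columns) 0/1 design matrix.
#' @export
build_fir_design <- function(timings, run_length_trs, extra_lags = 25) {
  if (inherits(timings, "condition_timing")) timings <- list(timings)
  if (length(timings) == 0L) .stopf("no condition timings supplied")
  blocks <- list()
  for (tm in timings) {
    stopifnot(inherits(tm, "condition_timing"))
    if (any(tm$block_onsets + tm$block_durations > run_length_trs)) {
      .stopf("condition '%s': block extends past run end (%d TRs)",
             tm$condition_name, run_length_trs)
    }
    maxdur <- max(tm$block_durations)
    ncol_c <- maxdur + extra_lags
    X <- matrix(0, run_length_trs, ncol_c)
    for (b in seq_along(tm$block_onsets)) {
      o <- tm$block_onsets[b]; d <- tm$block_durations[b]
      for (t in seq_len(d)) {            # within-block offsets 0..d-1
        row <- o + t                      # 1-based row for 0-based TR o+t-1
        if (row <= run_length_trs) X[row, t] <- 1
      }
      for (l in seq_len(extra_lags)) {    # post-offset lags 1..extra_lags
        row <- o + d + l                  # 1-based row for 0-based TR o+d+l-1
        if (row <= run_length_trs) X[row, maxdur + l] <- 1
      }
    }
    colnames(X) <- c(paste0(tm$condition_name, "_t", seq_len(maxdur) - 1L),
                     paste0(tm$condition_name, "_lag", seq_len(extra_lags)))
    blocks[[length(blocks) + 1L]] <- X
  }
  do.call(cbind, blocks)
}

#' Residualize time series against a design
#'
#' Ordinary least-squares residuals per region. An intercept and a linear
#' trend are prepended by default (de-meaning and de-trending). Rank-deficient
#' designs are handled by the pivoting QR (pseudoinverse path) with a warning.
#'
#' @param ts Matrix or [parcellated_ts], T x regions.
#' @param design T x k design matrix (may be `NULL` for de-mean/de-trend only).
#' @param add_mean_and_trend Prepend intercept and linear trend (default TRUE).
#' @return Same type as `ts`, residualized.
#' @export
residualize <- function(ts, design = NULL, add_mean_and_trend = TRUE) {
  y <- .ts_values(ts)
  Tn <- nrow(y)
  X <- design
  if (!is.null(X)) {
    X <- as.matrix(X)
    if (nrow(X) != Tn) .stopf("design rows (%d) do not match timepoints (%d)",
                              nrow(X), Tn)
  }
  if (add_mean_and_trend) {
    X <- cbind(intercept = 1, trend = seq_len(Tn) - (Tn + 1) / 2, X)
  }
  if (is.null(X)) return(ts)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    .warnf("design is rank deficient (rank %d of %d columns); pseudoinverse used",
           qrX$rank, ncol(X))
  }
  res <- y - qr.fitted(qrX, y)
  if (inherits(ts, "parcellated_ts")) {
    parcellated_ts(res, run = ts$run, state = ts$state, subject = ts$subject)
  } else {
    res
  }
}

#' Z-normalize each run of a time series
#'
#' Per run and per region: subtract the mean and divide by the standard
#' deviation, so variances are on the same scale across runs before
#' concatenation.
#'
#' @param ts A [parcellated_ts] (run labels used) or a matrix (one run).
#' @return Same type, normalized.
#' @export
znormalize_runs <- function(ts) {
  y <- .ts_values(ts)
  run <- if (inherits(ts, "parcellated_ts")) ts$run else rep("run1", nrow(y))
  out <- y
  for (r in unique(run)) {
    sel <- run == r
    if (sum(sel) < 2L) .stopf("run '%s' has fewer than 2 timepoints", r)
    block <- y[sel, , drop = FALSE]
    sdv <- apply(block, 2, stats::sd)
    if (any(sdv == 0)) {
      .stopf("zero-variance region(s) %s within run '%s'",
             paste(which(sdv == 0), collapse = ", "), r)
    }
    out[sel, ] <- scale(block)
  }
  if (inherits(ts, "parcellated_ts")) {
    parcellated_ts(out, run = ts$run, state = ts$state, subject = ts$subject)
  } else {
    out
  }
}

#' On-task TR mask
#'
#' TRUE exactly within task blocks (the union over conditions); used to
#' restrict task FC estimation to on-task timepoints.
#'
#' @param timings List of [condition_timing] objects (or one).
#' @param run_length_trs Run length in TRs.
#' @return Logical vector of length `run_length_trs`.
#' @export
select_on_task_trs <- function(timings, run_length_trs) {
  if (inherits(timings, "condition_timing")) timings <- list(timings)
  mask <- logical(run_length_trs)
  for (tm in timings) {
    stopifnot(inherits(tm, "condition_timing"))
    for (b in seq_along(tm$block_onsets)) {
      o <- tm$block_onsets[b]; d <- tm$block_durations[b]
      if (o + 1 > run_length_trs) next
      mask[(o + 1):(min(o + d, run_length_trs))] <- TRUE
    }
  }
  if (!any(mask)) .warnf("no on-task TRs: empty mask")
  mask
}

#' Drop the first frames of each run
#'
#' Convenience for the conventional removal of initial non-steady-state
#' frames before any modelling.
#'
#' @param ts A [parcellated_ts].
#' @param n_frames Frames to drop per run (default 5).
#' @return A [parcellated_ts].
#' @export
drop_initial_frames <- function(ts, n_frames = 5) {
  stopifnot(inherits(ts, "parcellated_ts"))
  keep <- unlist(lapply(split(seq_along(ts$run), factor(ts$run, unique(ts$run))),
                        function(i) utils::tail(i, -n_frames)), use.names = FALSE)
  keep <- sort(keep)
  parcellated_ts(ts$values[keep, , drop = FALSE], run = ts$run[keep],
                 state = ts$state, subject = ts$subject)
}
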