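# Nuisance/FIR design construction and residualization.

test_that("nuisance design has the canonical 64 labeled columns", {
  set.seed(1)
  Tn <- 100
  X <- build_nuisance_regressors(matrix(rnorm(Tn * 6), Tn),
                                 matrix(rnorm(Tn * 5), Tn),
                                 matrix(rnorm(Tn * 5), Tn))
  expect_equal(ncol(X), 64L)
  expect_equal(length(unique(colnames(X))), 64L)
  # 24 motion-derived + 40 physiological-derived
  expect_equal(sum(grepl("^motion", colnames(X))), 24L)
  expect_equal(sum(grepl("^(wm|vent)", colnames(X))), 40L)
})

test_that("derivatives and quadratics follow their definitions", {
  Tn <- 3
  motion <- cbind(c(1, 2, 3), matrix(5, Tn, 5))  # col 2..6 constant
  X <- build_nuisance_regressors(motion, matrix(rnorm(Tn * 5), Tn),
                                 matrix(rnorm(Tn * 5), Tn))
  expect_equal(unname(X[, "motion_d2"]), c(0, 0, 0))   # derivative of constant
  expect_equal(unname(X[, "motion1_sq"]), c(1, 4, 9))  # elementwise square
  expect_equal(unname(X[, "motion_d1"]), c(0, 1, 1))   # backward difference
})

test_that("nuisance input validation catches shape errors", {
  expect_error(build_nuisance_regressors(matrix(0, 10, 5), matrix(0, 10, 5),
                                         matrix(0, 10, 5)), "6 columns")
  expect_error(build_nuisance_regressors(matrix(0, 10, 6), matrix(0, 9, 5),
                                         matrix(0, 10, 5)), "row counts")
})

test_that("FIR column counts follow max-duration + lags per condition", {
  tA <- condition_timing("A", block_onsets = c(10, 60), block_durations = 10)
  X <- build_fir_design(tA, run_length_trs = 200, extra_lags = 25)
  expect_equal(ncol(X), 35L)
  tB <- condition_timing("B", block_onsets = c(120), block_durations = 8)
  XB <- build_fir_design(list(tA, tB), run_length_trs = 200, extra_lags = 25)
  expect_equal(ncol(XB), 35L + 33L)
  # pooled across blocks: the offset-0 column marks both block onsets
  expect_equal(which(X[, "A_t0"] == 1), c(11L, 61L))
})

test_that("FIR lags at the run end are truncated but columns retained", {
  tm <- condition_timing("A", block_onsets = 180, block_durations = 10)
  X <- build_fir_design(tm, run_length_trs = 200, extra_lags = 25)
  expect_equal(ncol(X), 35L)                # all columns retained
  expect_equal(sum(X[, "A_lag10"]), 1)      # lag 10 lands on TR 199 (0-based)
  expect_equal(sum(X[, "A_lag11"]), 0)      # lag 11 would be TR 200: absent
  expect_error(build_fir_design(list(), 100), "no condition timings")
})

test_that("condition timing invariants are enforced", {
  expect_error(condition_timing("A", c(10, 5), 3), "strictly increasing")
  expect_error(condition_timing("A", c(0, 2), 3), "overlap")
  expect_error(condition_timing("A", 95, 10, run_length_trs = 100), "past run end")
  expect_error(condition_timing("A", integer(0), 3), "no blocks")
})

test_that("residualize matches an independent normal-equations solver", {
  set.seed(3)
  X <- matrix(rnorm(200), 50, 4)
  Y <- matrix(rnorm(150), 50, 3)
  res <- residualize(Y, X, add_mean_and_trend = FALSE)
  expect_lt(max(abs(res - oracle_ols_residuals(Y, X))), 1e-10)
  # projection: applying twice changes nothing
  res2 <- residualize(res, X, add_mean_and_trend = FALSE)
  expect_lt(max(abs(res2 - res)), 1e-10)
})

test_that("residualize degenerate designs behave as projections should", {
  set.seed(4)
  y <- matrix(rnorm(60), 60, 1)
  # the series itself as a regressor: residual vanishes
  expect_lt(max(abs(residualize(y, y, add_mean_and_trend = FALSE))), 1e-10)
  # orthogonal design: residual equals the de-meaned series
  x <- matrix(rnorm(60), 60, 1)
  x <- x - mean(x)
  yc <- y - mean(y)
  x <- x - drop(crossprod(x, yc) / crossprod(yc, yc)) * yc  # force orthogonality
  res <- residualize(y, x, add_mean_and_trend = TRUE)
  detr <- residualize(y, NULL, add_mean_and_trend = TRUE)
  # x explains nothing beyond trend removal up to its overlap with the trend
  expect_lt(max(abs(residualize(yc, x, add_mean_and_trend = FALSE) - yc)), 1e-10)
  # rank-deficient design warns and still projects
  expect_warning(residualize(y, cbind(x, x), add_mean_and_trend = FALSE),
                 "rank deficient")
})

test_that("z-normalization gives per-run unit scale and is idempotent", {
  set.seed(5)
  ts <- parcellated_ts(rbind(matrix(rnorm(60, sd = 3), 30, 2),
                             matrix(rnorm(60, sd = 0.2), 30, 2)),
                       run = rep(c("r1", "r2"), each = 30))
  z <- znormalize_runs(ts)
  for (r in c("r1", "r2")) {
    blk <- z$values[z$run == r, ]
    expect_lt(max(abs(colMeans(blk))), 1e-12)
    expect_lt(max(abs(apply(blk, 2, sd) - 1)), 1e-12)
  }
  z2 <- znormalize_runs(z)
  expect_equal(z2$values, z$values, tolerance = 1e-12)
  # zero-variance region errors with names
  bad <- parcellated_ts(cbind(rnorm(10), rep(1, 10)), run = "r1")
  expect_error(znormalize_runs(bad), "region\\(s\\) 2 within run 'r1'")
})

test_that("on-task mask is the union of blocks", {
  tA <- condition_timing("A", c(0, 100), 50)
  expect_equal(sum(select_on_task_trs(tA, 200)), 100L)
  tB <- condition_timing("B", 25, 50)  # overlaps A's first block
  mask <- select_on_task_trs(list(tA, tB), 200)
  expect_equal(sum(mask), 125L)  # union counts each TR once
  expect_warning(
    mask0 <- select_on_task_trs(condition_timing("C", 300, 10), 200),
    "empty mask")
  expect_false(any(mask0))
})

test_that("initial frame removal drops frames per run", {
  ts <- parcellated_ts(matrix(seq_len(40), 20, 2), run = rep(c("a", "b"), each = 10))
  out <- drop_initial_frames(ts, 5)
  expect_equal(nrow(out$values), 10L)
  expect_equal(out$values[, 1], c(6:10, 16:20))
})
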