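# Activity-flow prediction, evaluation pooling, and model comparison.

test_that("actflow prediction matches the hand-evaluated weighted sum", {
  fc <- matrix(0.5, 3, 3); diag(fc) <- 1
  act <- matrix(c(1, 2, 3), 3, 1)
  expect_equal(unname(actflow_predict(act, fc)), matrix(c(2.5, 2.0, 1.5), 3, 1))
  # empty connectivity predicts zero
  expect_equal(actflow_predict(act, matrix(0, 3, 3)), matrix(0, 3, 1),
               ignore_attr = TRUE)
  expect_error(actflow_predict(matrix(0, 4, 1), matrix(0, 3, 3)), "does not match")
})

test_that("actflow is linear and self-excluding", {
  set.seed(60)
  fc <- random_corr(6, seed = 61)
  x <- matrix(rnorm(18), 6, 3); y <- matrix(rnorm(18), 6, 3)
  expect_equal(actflow_predict(2 * x + 3 * y, fc),
               2 * actflow_predict(x, fc) + 3 * actflow_predict(y, fc),
               tolerance = 1e-12)
  # prediction for region j never depends on act[j, ]
  x2 <- x; x2[4, ] <- x2[4, ] + 100
  expect_equal(actflow_predict(x, fc)[4, ], actflow_predict(x2, fc)[4, ],
               tolerance = 1e-12)
})

test_that("evaluation pools per-subject correlations via Fisher z", {
  set.seed(62)
  n <- 5
  actual <- lapply(1:n, function(i) matrix(rnorm(40), 8, 5))
  pred <- lapply(1:n, function(i) actual[[i]] + 0.5 * matrix(rnorm(40), 8, 5))
  ev <- evaluate_predictions(pred, actual)
  # independent oracle: per-subject r, mean of z, back-transform
  oracle_global <- tanh(mean(sapply(1:n, function(i)
    atanh(cor(as.vector(pred[[i]]), as.vector(actual[[i]]))))))
  expect_equal(ev$global_r, oracle_global, tolerance = 1e-12)
  oracle_region1 <- tanh(mean(sapply(1:n, function(i)
    atanh(cor(pred[[i]][1, ], actual[[i]][1, ])))))
  expect_equal(ev$per_region_r[1], oracle_region1, tolerance = 1e-12)
  # estimate-then-average differs from the (wrong) average-then-estimate path
  avg_pred <- Reduce(`+`, pred) / n
  avg_act <- Reduce(`+`, actual) / n
  wrong <- cor(as.vector(avg_pred), as.vector(avg_act))
  expect_gt(abs(ev$global_r - wrong), 1e-3)
  # perfect prediction: every r = 1
  ev1 <- evaluate_predictions(actual, actual)
  expect_true(all(ev1$per_region_r == 1))
  expect_equal(ev1$global_r, 1)
})

test_that("shuffled predictions have near-zero accuracy and NA is not silent", {
  set.seed(63)
  actual <- list(matrix(rnorm(2000), 10, 200))
  pred <- list(actual[[1]][, sample(200)])
  ev <- evaluate_predictions(pred, actual)
  expect_lt(max(abs(ev$per_region_r)), 0.2)
  expect_lt(abs(mean(ev$per_region_r)), 0.05)
  # zero-variance unit reported as NA with a warning
  a2 <- actual
  a2[[1]][3, ] <- 7
  expect_warning(ev2 <- evaluate_predictions(pred, a2), "undefined")
  expect_true(is.na(ev2$per_region_r[3]))
})

test_that("model comparison finds no differences between identical models", {
  set.seed(64)
  actual <- lapply(1:6, function(i) matrix(rnorm(40), 8, 5))
  pred <- lapply(actual, function(a) a + 0.3 * matrix(rnorm(40), 8, 5))
  ev <- evaluate_predictions(pred, actual)
  tab <- compare_prediction_models(ev, ev)
  expect_true(all(tab$t == 0))
  expect_true(all(tab$favors == ""))
  expect_error(compare_prediction_models(
    evaluate_predictions(pred[1:2], actual[1:2]),
    evaluate_predictions(pred[1:2], actual[1:2])), ">= 3 subjects")
})

test_that("a better connectivity model wins most regions in simulation", {
  set.seed(65)
  n_sub <- 30
  fc_true <- random_corr(10, seed = 66)
  fc_noisy <- stats::cov2cor(fc_true + 0.8 * crossprod(matrix(rnorm(100), 10, 10)) / 10)
  preds_a <- preds_b <- actuals <- vector("list", n_sub)
  for (i in seq_len(n_sub)) {
    out <- simulate_actflow_activations(fc_true, n_conditions = 20, seed = 100 + i)
    target <- out$activations - out$inputs  # the predictable component
    actuals[[i]] <- target + 0.2 * matrix(rnorm(length(target)), nrow(target))
    preds_a[[i]] <- actflow_predict(out$activations, out$weights)
    preds_b[[i]] <- actflow_predict(out$activations, fc_noisy * 0.5)
  }
  ev_a <- evaluate_predictions(preds_a, actuals)
  ev_b <- evaluate_predictions(preds_b, actuals)
  tab <- compare_prediction_models(ev_a, ev_b)
  expect_gt(attr(tab, "pct_favor_a"), 60)
  expect_equal(attr(tab, "pct_favor_b"), 0)
})
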