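# Per-edge latent FC estimation, LOSO exclusion, the average baseline, and
# loading summaries.

test_that("latent scores recover the generating latent edges better than any
           single state", {
  sim <- simulate_fc_stack(150, 4, 6, 0.7, seed = 50)
  fit <- latent_fc(sim$stack)
  eta <- sim$truth$latent_edge_scores
  E <- ncol(fit$scores)
  wins <- vapply(seq_len(E), function(e) {
    r_latent <- abs(cor(fit$scores[, e], eta[, e]))
    r_single <- max(abs(cor(sim$stack$values[, , e], eta[, e])))
    r_latent > r_single
  }, logical(1))
  expect_gt(mean(wins), 0.9)
})

test_that("LOSO drops the excluded state before fitting", {
  sim <- simulate_fc_stack(60, 4, 9, 0.6, seed = 51)
  fit <- latent_fc(sim$stack, exclude_state = "state3")
  expect_equal(nrow(fit$loadings), 8L)
  expect_false("state3" %in% rownames(fit$loadings))
  expect_equal(fit$excluded_state, "state3")
  # non-circularity: corrupting the excluded state's values changes nothing
  stack2 <- sim$stack
  stack2$values[, 3, ] <- 999
  fit2 <- latent_fc(stack2, exclude_state = "state3")
  expect_identical(fit$scores, fit2$scores)
  expect_identical(fit$loadings, fit2$loadings)
})

test_that("too few included states or subjects is refused", {
  sim <- simulate_fc_stack(30, 3, 3, 0.7, seed = 52)
  expect_error(latent_fc(sim$stack, exclude_state = "state1"), ">= 3 included")
  sim2 <- simulate_fc_stack(5, 3, 4, 0.7, seed = 52)
  expect_error(latent_fc(sim2$stack), ">= 10 subjects")
})

test_that("near-identical states reproduce the common matrix's edge ranking", {
  set.seed(53)
  N <- 40; R <- 5; E <- R * (R - 1) / 2
  base <- matrix(rnorm(N * E), N, E)
  vals <- array(NA_real_, c(N, 4, E))
  for (s in 1:4) vals[, s, ] <- base + 1e-3 * matrix(rnorm(N * E), N, E)
  stack <- fc_stack(vals, n_regions = R)
  fit <- latent_fc(stack)
  # group-matrix edge ranking identical to the common matrix's mean edges
  expect_equal(cor(vectorize_edges(fit$group_matrix), colMeans(base),
                   method = "spearman"), 1, tolerance = 1e-9)
})

test_that("zero-variance edges fall back to the restricted model with a flag", {
  sim <- simulate_fc_stack(30, 3, 4, 0.7, seed = 54)
  stack <- sim$stack
  stack$values[, , 2] <- 0.5  # constant edge across subjects and states
  expect_message(fit <- latent_fc(stack), "fell back")
  expect_true(fit$flagged[2])
  expect_false(any(fit$flagged[-2]))
})

test_that("average_fc is the mean over states and equals the restricted path", {
  sim <- simulate_fc_stack(25, 3, 4, 0.7, seed = 55)
  avg <- average_fc(sim$stack)
  # hand check one cell
  expect_equal(unname(avg[3, 2]), mean(sim$stack$values[3, , 2]))
  # definitional equivalence with restricted_average_solution, every edge
  for (e in seq_len(dim(sim$stack$values)[3])) {
    expect_equal(unname(avg[, e]),
                 unname(restricted_average_solution(sim$stack$values[, , e])$scores),
                 tolerance = 1e-15)
  }
  # exclusion
  avg2 <- average_fc(sim$stack, exclude_state = "state1")
  expect_equal(unname(avg2[1, 1]), mean(sim$stack$values[1, 2:4, 1]))
})

test_that("average and latent scores converge under equal generating loadings", {
  sim <- simulate_fc_stack(300, 8, 9, 0.7, seed = 56)
  fit <- latent_fc(sim$stack)
  avg <- average_fc(sim$stack)
  rs <- vapply(seq_len(nrow(avg)), function(i) cor(avg[i, ], fit$scores[i, ]),
               numeric(1))
  expect_gt(min(rs), 0.9)
  expect_gt(mean(rs), 0.95)
})

test_that("loading summaries count inclusively and detect null states", {
  lam <- matrix(0.8, 5, 3)
  lam[5, ] <- 0  # a state with no common variance
  sim <- simulate_fc_stack(500, 3, 5, loading_spec = lam, seed = 57)
  fit <- latent_fc(sim$stack)
  tab <- summarize_loadings(fit)
  expect_equal(tab$pct_at_threshold[1:4], rep(100, 4), tolerance = 5)
  expect_lt(tab$pct_at_threshold[5], 5)
  expect_gt(min(tab$pct_nonnegative[1:4]), 95)
  # inclusive threshold: a loading exactly at 0.4 counts
  fake <- fit
  fake$loadings <- matrix(c(0.4, 0.39, 0.41), 1, 3)
  rownames(fake$loadings) <- "s"
  expect_equal(summarize_loadings(fake, 0.4)$pct_at_threshold, 100 * 2 / 3)
})

test_that("edge fits are order-independent (pure per-edge computation)", {
  sim <- simulate_fc_stack(40, 4, 4, 0.7, seed = 58)
  fit <- latent_fc(sim$stack)
  # permute the edge dimension, refit, unpermute: identical results
  E <- dim(sim$stack$values)[3]
  perm <- rev(seq_len(E))
  stack_p <- sim$stack
  stack_p$values <- sim$stack$values[, , perm]
  fit_p <- latent_fc(stack_p)
  expect_equal(fit_p$scores[, order(perm)], fit$scores, tolerance = 1e-12)
  expect_equal(fit_p$loadings[, order(perm)], fit$loadings, tolerance = 1e-12)
})

test_that("model methods expose scores and predictions coherently", {
  sim <- simulate_fc_stack(30, 4, 4, 0.7, seed = 59)
  fit <- latent_fc(sim$stack)
  expect_identical(coef(fit), fit$loadings)
  m1 <- latent_fc_matrix(fit, 1)
  expect_equal(vectorize_edges(m1), fit$scores[1, ])
  act <- matrix(rnorm(8), 4, 2)
  expect_equal(predict(fit, act),
               actflow_predict(act, fit$group_matrix))
  # simulate() round-trips the generative structure deterministically
  s1 <- simulate(fit, seed = 9)
  s2 <- simulate(fit, seed = 9)
  expect_identical(s1$values, s2$values)
  res <- residuals(fit, sim$stack)
  expect_equal(dim(res), dim(sim$stack$values))
})
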