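# Single-factor extraction, regression scores, and the restricted
# equal-loading (average) model.

test_that("construction-inversion recovers loadings to 1e-6", {
  # fitting R = lam lam' + diag(1 - lam^2) must invert the construction
  for (lam in list(c(0.8, 0.7, 0.6), c(0.9, 0.5, 0.3, 0.7), rep(0.6, 5))) {
    R <- tcrossprod(lam) + diag(1 - lam^2)
    for (m in c("minres", "ml")) {
      fit <- fit_single_factor(R, method = m)
      expect_lt(max(abs(coef(fit) - lam)), 1e-6)
      expect_true(fit$converged)
      # standardized identity: lambda^2 + uniqueness = 1
      expect_lt(max(abs(fit$loadings^2 + fit$uniquenesses - 1)), 1e-6)
    }
  }
})

test_that("no common variance means no common factor", {
  # population identity: loadings vanish
  fit <- fit_single_factor(diag(4))
  expect_lt(max(abs(coef(fit))), 0.05)
  # sampled independent indicators: the least-squares optimum concentrates on
  # a single indicator (its uniqueness hits the floor) — a Heywood case that
  # must be flagged, with no appreciable loading on the other indicators
  set.seed(10)
  x <- matrix(rnorm(10000 * 4), 10000, 4)
  fit2 <- fit_single_factor(x)
  expect_true(fit2$heywood || max(abs(coef(fit2))) < 0.05)
  expect_lt(sort(abs(coef(fit2)), decreasing = TRUE)[2], 0.05)
})

test_that("loadings are sign-aligned so their sum is nonnegative", {
  lam <- c(-0.8, -0.7, -0.6)
  R <- tcrossprod(lam) + diag(1 - lam^2)
  fit <- fit_single_factor(R)
  expect_gte(sum(coef(fit)), 0)
  expect_lt(max(abs(coef(fit) - abs(lam))), 1e-6)
})

test_that("minres and ML agree on well-conditioned population matrices", {
  lam <- c(0.75, 0.6, 0.5, 0.65, 0.7)
  R <- tcrossprod(lam) + diag(1 - lam^2)
  f1 <- fit_single_factor(R, method = "minres")
  f2 <- fit_single_factor(R, method = "ml")
  expect_lt(max(abs(coef(f1) - coef(f2))), 1e-3)
})

test_that("ML extraction matches the reference ML implementation on data", {
  set.seed(42)
  eta <- rnorm(800)
  lam <- c(0.8, 0.7, 0.6, 0.5)
  x <- sapply(lam, function(l) l * eta + sqrt(1 - l^2) * rnorm(800))
  ref <- stats::factanal(x, factors = 1)
  mine <- fit_single_factor(x, method = "ml")
  expect_lt(max(abs(abs(coef(mine)) - abs(as.vector(ref$loadings)))), 1e-4)
})

test_that("fewer than three indicators is refused as unidentified", {
  set.seed(1)
  expect_error(fit_single_factor(matrix(rnorm(40), 20, 2)), "unidentified")
  expect_error(fit_single_factor(matrix(rnorm(20), 4, 5)), "more subjects")
})

test_that("Heywood cases are clipped to the floor and flagged", {
  # a correlation matrix implying a communality > 1 for indicator 1
  R <- matrix(c(1, .9, .9,
                .9, 1, .6,
                .9, .6, 1), 3, 3)
  fit <- fit_single_factor(R)
  expect_true(fit$heywood)
  expect_gte(min(fit$uniquenesses), 0.001 - 1e-12)
})

test_that("regression scores behave at the exchangeable and degenerate limits", {
  set.seed(20)
  sim <- simulate_fc_stack(400, 3, 4, 0.7, seed = 20)
  ind <- scale(sim$stack$values[, , 1])  # standardized indicators
  fit <- fit_single_factor(ind)
  sc <- regression_scores(fit, ind)
  # normalization contract
  expect_lt(abs(mean(sc)), 1e-12)
  expect_equal(sd(sc), 1, tolerance = 1e-12)
  # exactly exchangeable solution: scores are a monotone map of row means
  lam_eq <- rep(0.7, 4)
  R_eq <- tcrossprod(lam_eq) + diag(1 - lam_eq^2)
  fit_eq <- fit_single_factor(R_eq)
  sc_eq <- regression_scores(fit_eq, ind)
  expect_equal(cor(sc_eq, rowMeans(ind), method = "spearman"), 1,
               tolerance = 1e-12)
  # a near-perfect indicator dominates the weights
  eta <- rnorm(400)
  ind2 <- cbind(eta + 0.001 * rnorm(400),
                0.5 * eta + sqrt(0.75) * rnorm(400),
                0.5 * eta + sqrt(0.75) * rnorm(400))
  fit2 <- suppressWarnings(fit_single_factor(ind2))
  sc2 <- regression_scores(fit2, ind2)
  expect_gt(abs(cor(sc2, ind2[, 1])), 0.999)
})

test_that("score validity matches the population formula", {
  # population validity of regression scores is sqrt(lam' R^-1 lam)
  lam <- c(0.8, 0.6, 0.7, 0.5)
  R <- tcrossprod(lam) + diag(1 - lam^2)
  validity <- sqrt(drop(t(lam) %*% solve(R) %*% lam))
  set.seed(30)
  N <- 10000
  eta <- rnorm(N)
  x <- sapply(lam, function(l) l * eta + sqrt(1 - l^2) * rnorm(N))
  fit <- fit_single_factor(x)
  sc <- regression_scores(fit, x)
  expect_equal(abs(cor(sc, eta)), validity, tolerance = 0.02)
})

test_that("restricted model scores are exact arithmetic row means", {
  ind <- rbind(c(1, 2, 3), c(4, 5, 6), c(0, 0, 3))
  rs <- restricted_average_solution(ind)
  expect_identical(rs$scores, rowMeans(ind))
  expect_equal(unname(rs$solution$loadings), rep(1, 3))
  expect_equal(unname(rs$solution$uniquenesses), rep(0, 3))
  # degenerate single indicator
  one <- matrix(c(5, 7, 9), 3, 1)
  expect_equal(restricted_average_solution(one)$scores, c(5, 7, 9))
})

test_that("free and restricted scores agree when generating loadings are equal", {
  sim <- simulate_fc_stack(2000, 3, 5, 0.7, seed = 40)
  ind <- sim$stack$values[, , 2]
  free <- regression_scores(fit_single_factor(ind), ind)
  restricted <- restricted_average_solution(ind)$scores
  expect_gt(cor(free, restricted), 0.99)
})
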