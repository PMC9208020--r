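# Single-factor model: minres / ML extraction on a correlation matrix,
# regression-method (Thurstone) factor scores, and the restricted equal-loading
# model whose scores reduce to the arithmetic average of the indicators.

#' Fit a single-factor model
#'
#' Fits the one-factor model `R = lambda lambda' + diag(uniqueness)` to a set
#' of indicators. In the standardized metric each indicator decomposes into a
#' common part (loading `lambda`, so `lambda^2` is the variance shared with the
#' factor) and a unique part (`uniqueness = 1 - lambda^2`). Extraction is by
#' minimum residual (minres: least squares on the off-diagonal correlations)
#' or Gaussian maximum likelihood.
#'
#' Loadings are sign-aligned so that their sum is nonnegative. Solutions
#' implying negative unique variance (Heywood cases) are clipped to the
#' `heywood_floor` and flagged.
#'
#' @param x Either an N x S numeric matrix of indicators (subjects in rows,
#'   states/measures in columns, N > S), or an S x S correlation matrix
#'   (recognized by symmetry and a unit diagonal), in which case the model is
#'   fit to it directly and no scores can be computed without data.
#' @param method `"minres"` (default) or `"ml"`.
#' @param heywood_floor Lower bound on uniquenesses (default 0.001).
#' @param max_iter,tol Optimizer iteration cap and convergence tolerance.
#' @return An object of class `single_factor` with elements `loadings`,
#'   `uniquenesses`, `score_weights`, `correlation` (the matrix the fit used),
#'   `converged`, `heywood`, `method`, `n_obs`, `state_labels`.
#' @seealso [regression_scores()], [restricted_average_solution()]
#' @examples
#' lam <- c(0.8, 0.7, 0.6)
#' R <- tcrossprod(lam) + diag(1 - lam^2)
#' fit <- fit_single_factor(R)
#' coef(fit)  # recovers lam
#' @export
fit_single_factor <- function(x, method = c("minres", "ml"),
                              heywood_floor = 0.001, max_iter = 1000,
                              tol = 1e-8) {
  method <- match.arg(method)
  x <- as.matrix(x)
  is_cor <- .is_square_matrix(x) && max(abs(x - t(x))) < 1e-10 &&
    max(abs(diag(x) - 1)) < 1e-10
  if (is_cor) {
    R <- x
    n_obs <- NA_integer_
  } else {
    if (anyNA(x)) .stopf("indicators contain missing values")
    if (nrow(x) <= ncol(x)) {
      .stopf("need more subjects (%d) than indicators (%d)", nrow(x), ncol(x))
    }
    sdv <- apply(x, 2, stats::sd)
    if (any(sdv == 0)) {
      .stopf("indicator column(s) %s have zero variance",
             paste(which(sdv == 0), collapse = ", "))
    }
    R <- stats::cor(x)
    n_obs <- nrow(x)
  }
  S <- ncol(R)
  if (S < 3L) .stopf("single-factor model unidentified with %d indicators (need >= 3)", S)
  labels <- colnames(R) %||% paste0("state", seq_len(S))

  fit <- switch(method,
                minres = .fit_minres(R, heywood_floor, max_iter, tol),
                ml = .fit_ml(R, heywood_floor, max_iter, tol))
  lambda <- fit$lambda
  if (sum(lambda) < 0) lambda <- -lambda
  heywood <- fit$heywood
  uniq <- pmax(1 - lambda^2, heywood_floor)
  if (any(1 - lambda^2 < heywood_floor - 1e-12)) heywood <- TRUE
  if (!fit$converged) {
    .warnf("single-factor %s fit did not converge within %d iterations", method, max_iter)
  }
  names(lambda) <- names(uniq) <- labels
  sol <- structure(list(loadings = lambda, uniquenesses = uniq,
                        correlation = R, converged = fit$converged,
                        heywood = heywood, method = method,
                        heywood_floor = heywood_floor,
                        n_obs = n_obs, state_labels = labels,
                        restricted = FALSE),
                   class = "single_factor")
  sol$score_weights <- .thurstone_weights(sol)
  sol
}

# minres: minimize the off-diagonal squared residuals sum_{i<j}
# (r_ij - l_i l_j)^2, parameterized over the uniquenesses psi with the loading
# taken from the leading eigen-pair of R with communalities 1 - psi on the
# diagonal (the standard psychometrics formulation; avoids the degenerate
# axis-concentrated loading direction of a direct-lambda search).
.fit_minres <- function(R, heywood_floor, max_iter, tol) {
  S <- ncol(R)
  lambda_of <- function(psi) {
    M <- R
    diag(M) <- 1 - psi
    eg <- eigen(M, symmetric = TRUE)
    eg$vectors[, 1] * sqrt(max(eg$values[1], 0))
  }
  obj <- function(psi) {
    l <- lambda_of(psi)
    Rt <- R - tcrossprod(l)
    sum(Rt[upper.tri(Rt)]^2)
  }
  # start from squared multiple correlations when invertible, else 0.5
  smc <- tryCatch(1 - 1 / diag(solve(R)), error = function(e) rep(0.5, S))
  start <- pmin(pmax(1 - smc, heywood_floor * 2), 1)
  op <- stats::optim(start, obj, method = "L-BFGS-B",
                     lower = rep(heywood_floor, S), upper = rep(1, S),
                     control = list(maxit = max_iter, factr = 10,
                                    pgtol = tol * 1e-2))
  op <- stats::optim(op$par, obj, method = "L-BFGS-B",
                     lower = rep(heywood_floor, S), upper = rep(1, S),
                     control = list(maxit = max_iter, factr = 10,
                                    pgtol = tol * 1e-2))
  at_floor <- any(op$par < heywood_floor * (1 + 1e-6))
  list(lambda = lambda_of(op$par), converged = op$convergence %in% c(0L, 52L),
       heywood = at_floor)
}

# ML via the concentrated likelihood over uniquenesses: given psi, the loading
# is the leading eigen-pair of psi^{-1/2} R psi^{-1/2}; the discrepancy is the
# sum over the discarded eigenvalues of (theta - log theta - 1).
.fit_ml <- function(R, heywood_floor, max_iter, tol) {
  S <- ncol(R)
  start <- pmax(1 - 0.5 * abs(eigen(R, symmetric = TRUE)$vectors[, 1]) *
                  sqrt(eigen(R, symmetric = TRUE)$values[1]), 0.1)
  obj <- function(logpsi) {
    psi <- exp(logpsi)
    d <- 1 / sqrt(psi)
    Rs <- R * tcrossprod(d)
    th <- eigen(Rs, symmetric = TRUE, only.values = TRUE)$values
    sum(th[-1] - log(th[-1]) - 1)
  }
  ctrl <- list(maxit = max_iter, pgtol = tol * 1e-2, factr = 10)
  op <- stats::optim(log(start), obj, method = "L-BFGS-B",
                     lower = rep(log(heywood_floor), S), upper = rep(0, S),
                     control = ctrl)
  op <- stats::optim(op$par, obj, method = "L-BFGS-B",
                     lower = rep(log(heywood_floor), S), upper = rep(0, S),
                     control = ctrl)
  psi <- exp(op$par)
  d <- 1 / sqrt(psi)
  Rs <- R * tcrossprod(d)
  eg <- eigen(Rs, symmetric = TRUE)
  lambda <- sqrt(psi) * eg$vectors[, 1] * sqrt(max(eg$values[1] - 1, 0))
  at_floor <- any(psi < heywood_floor * (1 + 1e-6))
  list(lambda = lambda, converged = op$convergence %in% c(0L, 52L),
       heywood = at_floor)
}

# Thurstone regression-score weights W = R^{-1} lambda, with a ridge-stabilized
# inverse when R is (near-)singular.
.thurstone_weights <- function(sol) {
  R <- sol$correlation
  w <- tryCatch(solve(R, sol$loadings), error = function(e) NULL)
  if (is.null(w) || any(!is.finite(w))) {
    jitter <- 1e-8
    repeat {
      w <- tryCatch(solve(R + diag(jitter, ncol(R)), sol$loadings),
                    error = function(e) NULL)
      if (!is.null(w) && all(is.finite(w))) break
      jitter <- jitter * 10
      if (jitter > 1e-2) .stopf("indicator correlation matrix is numerically singular")
    }
    .warnf("singular indicator correlation matrix: ridge jitter %.1e applied", jitter)
  }
  names(w) <- sol$state_labels
  w
}

#' Regression-method (Thurstone) factor scores
#'
#' Applies the score weights `W = R^{-1} lambda` to the column-standardized
#' indicators and standardizes the resulting scores to mean 0, sd 1 across
#' subjects.
#'
#' @param solution A `single_factor` fit.
#' @param indicators N x S matrix on the same indicators the model was fit to.
#' @return Numeric vector of N standardized factor scores.
#' @export
regression_scores <- function(solution, indicators) {
  stopifnot(inherits(solution, "single_factor"))
  indicators <- as.matrix(indicators)
  if (ncol(indicators) != length(solution$loadings)) {
    .stopf("indicator count (%d) does not match the solution (%d)",
           ncol(indicators), length(solution$loadings))
  }
  if (isTRUE(solution$restricted)) {
    return(rowMeans(indicators))
  }
  z <- .standardize_cols(indicators)
  raw <- drop(z %*% solution$score_weights)
  .standardize_vec(raw)
}

#' Restricted equal-loading solution (the average model)
#'
#' The restricted single-factor model fixes all loadings at 1 and all unique
#' variances at 0; its factor scores are then exactly the per-subject
#' arithmetic means of the raw indicators. This is the "average FC" baseline
#' that latent FC is compared against.
#'
#' @param indicators N x S numeric matrix (S >= 1).
#' @return A list with the restricted `single_factor` solution and `scores`
#'   (raw row means, not standardized).
#' @export
restricted_average_solution <- function(indicators) {
  indicators <- as.matrix(indicators)
  S <- ncol(indicators)
  if (S < 1L) .stopf("need at least one indicator")
  labels <- colnames(indicators) %||% paste0("state", seq_len(S))
  lambda <- rep(1, S); names(lambda) <- labels
  uniq <- rep(0, S); names(uniq) <- labels
  w <- rep(1 / S, S); names(w) <- labels
  sol <- structure(list(loadings = lambda, uniquenesses = uniq,
                        score_weights = w,
                        correlation = if (S > 1 && nrow(indicators) > 2)
                          suppressWarnings(stats::cor(indicators)) else diag(S),
                        converged = TRUE, heywood = FALSE,
                        method = "restricted-average", heywood_floor = 0,
                        n_obs = nrow(indicators), state_labels = labels,
                        restricted = TRUE),
                   class = "single_factor")
  list(solution = sol, scores = rowMeans(indicators))
}

#' @export
print.single_factor <- function(x, ...) {
  cat(sprintf("Single-factor model (%s)%s\n", x$method,
              if (!x$converged) " [NOT CONVERGED]" else ""))
  tab <- rbind(loading = x$loadings, uniqueness = x$uniquenesses)
  print(round(tab, 3))
  if (x$heywood) cat("Heywood case: uniqueness clipped at the floor.\n")
  invisible(x)
}

#' @export
coef.single_factor <- function(object, ...) object$loadings

#' @export
summary.single_factor <- function(object, ...) {
  out <- list(loadings = object$loadings,
              uniquenesses = object$uniquenesses,
              score_weights = object$score_weights,
              variance_explained = mean(object$loadings^2),
              method = object$method,
              converged = object$converged,
              heywood = object$heywood)
  class(out) <- "summary.single_factor"
  out
}

#' @export
print.summary.single_factor <- function(x, ...) {
  cat(sprintf("Single-factor model (%s): mean variance explained %.3f\n",
              x$method, x$variance_explained))
  tab <- rbind(loading = x$loadings, uniqueness = x$uniquenesses,
               score_weight = x$score_weights)
  print(round(tab, 3))
  invisible(x)
}

#' @describeIn fit_single_factor factor scores for new indicator data.
#' @param object A `single_factor` fit.
#' @param newdata N x S indicator matrix to score.
#' @param ... Unused.
#' @export
predict.single_factor <- function(object, newdata, ...) {
  regression_scores(object, newdata)
}
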