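# Synthetic data with the statistical structure the latent-FC framework
# assumes: per-edge latent connectivity with state-specific loadings and
# unique Gaussian noise, BOLD-like time series with a target correlation,
# activations obeying the activity-flow generative rule, and behavioural
# measures loading on a g factor coupled to the latent edges.
#
# All generators are pure functions of their arguments: one integer seed
# expands into fixed per-stream substreams (subject/state/edge offsets), so
# e.g. increasing n_states leaves earlier states' draws unchanged.

#' Simulate a multi-state FC stack from the latent factor model
#'
#' Generates, for each edge e, latent scores `eta[i,e] ~ N(0,1)` and state
#' indicators `y[i,s,e] = lambda[s,e] * eta[i,e] + sqrt(1 - lambda[s,e]^2) *
#' noise`, so every indicator is standardized in population and `lambda^2` is
#' the variance shared with the latent edge. Edge-to-behaviour coupling
#' weights (used by [simulate_behavior()]) are drawn here too: a random
#' `coupling_prop` fraction of edges receives a weight of `coupling_effect`.
#'
#' @param n_subjects,n_regions,n_states Problem size (>= 3 each).
#' @param loading_spec Loadings in \[-1, 1\]: a scalar, a per-state vector, or
#'   a states x edges matrix.
#' @param seed Integer seed.
#' @param coupling_prop Fraction of edges coupled to the behavioural g factor.
#' @param coupling_effect Standardized weight on each coupled edge.
#' @return List with `stack` (an [fc_stack]) and `truth` (class
#'   `latent_ground_truth`): `latent_edge_scores` (subjects x edges eta),
#'   `state_loadings`, `unique_sd`, `coupling_weights`, `seed`.
#' @export
simulate_fc_stack <- function(n_subjects, n_regions, n_states, loading_spec = 0.7,
                              seed = 1, coupling_prop = 0.1,
                              coupling_effect = 0.5) {
  if (n_subjects < 3L) .stopf("n_subjects must be >= 3")
  if (n_regions < 3L) .stopf("n_regions must be >= 3")
  if (n_states < 3L) .stopf("n_states must be >= 3")
  E <- n_regions * (n_regions - 1) / 2
  lam <- .expand_loadings(loading_spec, n_states, E)
  bad <- which(abs(lam) > 1, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    .stopf("loading magnitude > 1 at state %d, edge %d (value %.3f)",
           bad[1, 1], bad[1, 2], lam[bad[1, 1], bad[1, 2]])
  }
  unique_sd <- sqrt(1 - lam^2)

  set.seed(.substream_seed(seed, 1))
  eta <- matrix(stats::rnorm(n_subjects * E), n_subjects, E)

  vals <- array(NA_real_, c(n_subjects, n_states, E))
  for (s in seq_len(n_states)) {
    set.seed(.substream_seed(seed, 2, s))
    noise <- matrix(stats::rnorm(n_subjects * E), n_subjects, E)
    vals[, s, ] <- eta * matrix(lam[s, ], n_subjects, E, byrow = TRUE) +
      noise * matrix(unique_sd[s, ], n_subjects, E, byrow = TRUE)
  }

  set.seed(.substream_seed(seed, 3))
  w <- numeric(E)
  n_coupled <- round(coupling_prop * E)
  if (n_coupled > 0) w[sample(E, n_coupled)] <- coupling_effect

  states <- paste0("state", seq_len(n_states))
  truth <- structure(list(latent_edge_scores = eta,
                          state_loadings = lam,
                          unique_sd = unique_sd,
                          coupling_weights = w,
                          n_regions = n_regions,
                          seed = seed),
                     class = "latent_ground_truth")
  list(stack = fc_stack(vals, n_regions = n_regions, state_labels = states),
       truth = truth)
}

.expand_loadings <- function(spec, n_states, n_edges) {
  if (is.matrix(spec)) {
    if (!all(dim(spec) == c(n_states, n_edges))) {
      .stopf("loading matrix must be %d states x %d edges", n_states, n_edges)
    }
    return(spec)
  }
  if (length(spec) == 1L) return(matrix(spec, n_states, n_edges))
  if (length(spec) == n_states) return(matrix(spec, n_states, n_edges))
  .stopf("loading_spec must be scalar, one value per state, or states x edges")
}

#' Simulate time series with a target population correlation
#'
#' Draws `n_timepoints` i.i.d. multivariate Gaussian samples whose population
#' correlation equals `target_fc` (via an eigen factorization of the target,
#' which must be positive semi-definite with unit diagonal).
#'
#' @param target_fc Square symmetric PSD matrix with unit diagonal.
#' @param n_timepoints Number of samples (> number of regions).
#' @param seed Integer seed.
#' @param state,subject Metadata for the returned [parcellated_ts].
#' @return A [parcellated_ts].
#' @export
simulate_timeseries_from_fc <- function(target_fc, n_timepoints, seed = 1,
                                        state = NA_character_,
                                        subject = NA_character_) {
  m <- unclass(as.matrix(target_fc))
  if (!.is_square_matrix(m)) .stopf("target FC must be square")
  .check_symmetric(m, what = "target FC")
  R <- nrow(m)
  if (n_timepoints <= R) {
    .stopf("n_timepoints (%d) must exceed the region count (%d)", n_timepoints, R)
  }
  eg <- eigen(m, symmetric = TRUE)
  if (min(eg$values) < -1e-8) {
    .stopf("target FC is not positive semi-definite (most negative eigenvalue %.3g)",
           min(eg$values))
  }
  A <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0)), R)
  set.seed(.substream_seed(seed, 4))
  z <- matrix(stats::rnorm(n_timepoints * R), n_timepoints, R)
  parcellated_ts(z %*% t(A), state = state, subject = subject)
}

#' Simulate activations under the activity-flow generative rule
#'
#' The activity-flow model predicts a region's activation as the
#' connectivity-weighted sum of all other regions' activations. This generator
#' inverts that rule: it draws per-condition input vectors `s` and solves
#' `(I - W) a = s`, where `W` is the zero-diagonal connectivity weight matrix,
#' so that `actflow_predict(a, W) = a - s` holds as an algebraic identity (the
#' prediction error is exactly the injected input). `W` is rescaled to
#' spectral radius `spectral_target` when it is not already below it, keeping
#' the fixed point well-conditioned; the factor is returned.
#'
#' @param fc Connectivity matrix (diagonal ignored).
#' @param n_conditions Number of task conditions.
#' @param input_scale SD of the injected inputs.
#' @param seed Integer seed.
#' @param spectral_target Spectral-radius bound applied by rescaling (0.9).
#' @return List with `activations` (regions x conditions), `inputs` (same
#'   shape), `weights` (the W actually used), `rescale_factor`.
#' @export
simulate_actflow_activations <- function(fc, n_conditions, input_scale = 1,
                                         seed = 1, spectral_target = 0.9) {
  W <- unclass(as.matrix(fc))
  if (!.is_square_matrix(W)) .stopf("fc must be square")
  diag(W) <- 0
  R <- nrow(W)
  ev <- abs(eigen(W, only.values = TRUE)$values)
  rho <- if (length(ev)) max(ev) else 0
  rescale <- 1
  if (!is.finite(rho)) .stopf("connectivity weights are not finite")
  if (rho >= spectral_target && rho > 0) {
    rescale <- spectral_target / rho
    W <- W * rescale
    message(sprintf("simulate_actflow_activations: spectral radius %.3f rescaled by %.3f",
                    rho, rescale))
  }
  set.seed(.substream_seed(seed, 5))
  s <- matrix(stats::rnorm(R * n_conditions, sd = 1), R, n_conditions) * input_scale
  a <- solve(diag(R) - W, s)
  list(activations = a, inputs = s, weights = W, rescale_factor = rescale)
}

#' Simulate behavioural measures loading on a g factor
#'
#' The general-intelligence factor is generated as the coupling-weighted sum
#' of the latent edge scores plus independent noise, then standardized; each
#' of the `n_measures` cognitive measures is `g_loadings[k] * g + unique
#' noise`, column-standardized. With the default 11 measures and loadings of
#' 0.7 this mirrors a typical cognitive battery's positive manifold.
#'
#' @param truth A `latent_ground_truth` from [simulate_fc_stack()].
#' @param n_measures Number of measures (>= 3; default 11).
#' @param g_loadings Scalar or per-measure loadings in \[-1, 1\].
#' @param noise_sd Unique noise SD per measure; default `sqrt(1 - g_loadings^2)`
#'   so measures are standardized in population.
#' @param g_noise_var Variance fraction of g not explained by the coupled
#'   edges (0.2 by default; ignored when all coupling weights are zero, in
#'   which case g is pure noise).
#' @param seed Integer seed.
#' @return List with `measures` (subjects x measures, standardized columns),
#'   `g_true` (standardized), `g_loadings`.
#' @export
simulate_behavior <- function(truth, n_measures = 11, g_loadings = 0.7,
                              noise_sd = NULL, g_noise_var = 0.2, seed = 1) {
  stopifnot(inherits(truth, "latent_ground_truth"))
  if (n_measures < 3L) .stopf("g factor unidentifiable with %d measures (need >= 3)",
                              n_measures)
  lam <- rep_len(g_loadings, n_measures)
  if (any(abs(lam) > 1)) .stopf("g loadings must lie in [-1, 1]")
  noise_sd <- noise_sd %||% sqrt(1 - lam^2)
  noise_sd <- rep_len(noise_sd, n_measures)
  N <- nrow(truth$latent_edge_scores)

  signal <- drop(truth$latent_edge_scores %*% truth$coupling_weights)
  set.seed(.substream_seed(seed, 6))
  if (all(truth$coupling_weights == 0)) {
    g <- stats::rnorm(N)
  } else {
    g <- sqrt(1 - g_noise_var) * .standardize_vec(signal) +
      sqrt(g_noise_var) * stats::rnorm(N)
  }
  g <- .standardize_vec(g)

  set.seed(.substream_seed(seed, 7))
  eps <- matrix(stats::rnorm(N * n_measures), N, n_measures)
  m <- outer(g, lam) + sweep(eps, 2, noise_sd, "*")
  # standardize columns unless degenerate (noiseless loadings-1 case keeps g)
  sdv <- apply(m, 2, stats::sd)
  m <- sweep(m, 2, colMeans(m), "-")
  m <- sweep(m, 2, ifelse(sdv > 0, sdv, 1), "/")
  colnames(m) <- paste0("measure", seq_len(n_measures))
  list(measures = m, g_true = g, g_loadings = lam)
}
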