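# TSV matrix readers/writers with JSON sidecars, and the configuration-driven
# pipeline that chains simulation -> FC stack -> latent/average FC -> held-out
# similarity -> activity flow -> behaviour prediction.

#' Write / read a labeled numeric matrix as TSV
#'
#' Matrices round-trip to 1e-12 (values are written at full precision).
#' An optional JSON sidecar (`<path>.json`) carries metadata. Reading
#' validates shape: ragged rows, non-numeric cells and duplicate labels are
#' errors naming the offending line.
#'
#' @param m Numeric matrix (row/col names written when present).
#' @param path Output TSV path.
#' @param sidecar Optional list written as `<path>.json`.
#' @export
write_matrix <- function(m, path, sidecar = NULL) {
  m <- as.matrix(m)
  df <- as.data.frame(format(m, digits = 17, trim = TRUE, scientific = TRUE),
                      stringsAsFactors = FALSE)
  rn <- rownames(m) %||% paste0("row", seq_len(nrow(m)))
  cn <- colnames(m) %||% paste0("col", seq_len(ncol(m)))
  lines <- c(paste(c("id", cn), collapse = "\t"),
             vapply(seq_len(nrow(m)),
                    function(i) paste(c(rn[i], df[i, ]), collapse = "\t"),
                    character(1)))
  writeLines(lines, path)
  if (!is.null(sidecar)) {
    jsonlite::write_json(sidecar, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_matrix
#' @param check_fc If TRUE, validate the result as an FC matrix (square,
#'   symmetric to 1e-8, unit diagonal) and return an [fc_matrix].
#' @return `read_matrix`: a labeled numeric matrix (or [fc_matrix]), with the
#'   sidecar (if present) in attribute `sidecar`.
#' @export
read_matrix <- function(path, check_fc = FALSE) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  lines <- readLines(path)
  if (length(lines) < 2L) .stopf("%s: need a header and at least one row", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- length(parts[[1]])
  for (i in seq_along(parts)) {
    if (length(parts[[i]]) != ncols) {
      .stopf("%s: line %d has %d fields, expected %d (ragged row)",
             path, i, length(parts[[i]]), ncols)
    }
  }
  cn <- parts[[1]][-1]
  if (anyDuplicated(cn)) .stopf("%s: duplicate column labels on line 1", path)
  rn <- vapply(parts[-1], `[[`, character(1), 1)
  if (anyDuplicated(rn)) {
    .stopf("%s: duplicate row label on line %d", path,
           which(duplicated(rn))[1] + 1L)
  }
  vals <- matrix(NA_real_, length(rn), length(cn), dimnames = list(rn, cn))
  for (i in seq_along(rn)) {
    v <- suppressWarnings(as.numeric(parts[[i + 1L]][-1]))
    if (anyNA(v)) .stopf("%s: non-numeric cell on line %d", path, i + 1L)
    vals[i, ] <- v
  }
  sidecar_path <- paste0(path, ".json")
  if (file.exists(sidecar_path)) {
    attr(vals, "sidecar") <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  }
  if (check_fc) {
    sc <- attr(vals, "sidecar")
    vals <- fc_matrix(vals, state = sc$state %||% NA_character_,
                      subject = sc$subject %||% NA_character_,
                      n_trs_used = sc$n_trs_used %||% NA_integer_)
  }
  vals
}

#' Pipeline run configuration
#'
#' Validates and normalizes the options of a full [run_pipeline()] run on
#' synthetic data.
#'
#' @param n_subjects,n_regions,n_states Problem size for the simulated cohort.
#' @param loading_spec Generating loadings (see [simulate_fc_stack()]).
#' @param exclude_state State held out for the LOSO analyses (label, or
#'   `NULL` for none).
#' @param method Factor extraction method.
#' @param n_conditions Task conditions for the activity-flow stage.
#' @param n_measures Behavioural measures.
#' @param alpha FDR level for comparisons.
#' @param seed Master seed; every stage derives its streams from it.
#' @return Object of class `run_config`.
#' @export
run_config <- function(n_subjects = 40, n_regions = 8, n_states = 5,
                       loading_spec = 0.7, exclude_state = "state1",
                       method = "minres", n_conditions = 6, n_measures = 11,
                       alpha = 0.05, seed = 1) {
  if (n_states < 4 && !is.null(exclude_state)) {
    .stopf("need >= 4 states to hold one out and still fit the factor model")
  }
  cfg <- list(n_subjects = n_subjects, n_regions = n_regions,
              n_states = n_states, loading_spec = loading_spec,
              exclude_state = exclude_state, method = method,
              n_conditions = n_conditions, n_measures = n_measures,
              alpha = alpha, seed = seed)
  class(cfg) <- "run_config"
  cfg
}

#' Run the full latent-FC pipeline on synthetic data
#'
#' Simulates a cohort, builds the FC stack, fits latent FC (full and
#' leave-one-state-out), the average-FC baseline, evaluates held-out-state
#' similarity, runs activity-flow prediction with latent vs single-state
#' connectivity, and predicts the simulated g factor from latent edges with
#' cross-sample ridge regression. Writes TSV/JSON artifacts and a manifest
#' carrying the seed and a config hash; a rerun with the same config and seed
#' reproduces the manifest hash.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list of the in-memory stage results plus `manifest`.
#' @export
run_pipeline <- function(config, out_dir = tempfile("latentfc_run_")) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "simulate"
  res <- tryCatch({
    sim <- simulate_fc_stack(config$n_subjects, config$n_regions,
                             config$n_states, config$loading_spec,
                             seed = config$seed)
    stage <- "latent"
    fit_full <- latent_fc(sim$stack, method = config$method)
    fit_loso <- if (!is.null(config$exclude_state)) {
      latent_fc(sim$stack, exclude_state = config$exclude_state,
                method = config$method)
    } else NULL
    avg <- average_fc(sim$stack)

    stage <- "similarity"
    similarity <- NULL
    if (!is.null(fit_loso)) {
      sidx <- match(config$exclude_state, sim$stack$state_labels)
      held <- sim$stack$values[, sidx, ]
      sim_latent <- vapply(seq_len(config$n_subjects), function(i) {
        stats::cor(fit_loso$scores[i, ], held[i, ])
      }, numeric(1))
      ref_state <- setdiff(seq_len(config$n_states), sidx)[1]
      sim_single <- vapply(seq_len(config$n_subjects), function(i) {
        stats::cor(sim$stack$values[i, ref_state, ], held[i, ])
      }, numeric(1))
      similarity <- compare_similarity(cbind(held_out = sim_latent),
                                       cbind(held_out = sim_single),
                                       alpha = config$alpha)
    }

    stage <- "actflow"
    gm <- fit_full$group_matrix
    act <- simulate_actflow_activations(gm, config$n_conditions,
                                        seed = config$seed)
    pred <- actflow_predict(act$activations, act$weights)
    actflow_eval <- evaluate_predictions(pred, act$activations - act$inputs)

    stage <- "behavior"
    beh <- simulate_behavior(sim$truth, n_measures = config$n_measures,
                             seed = config$seed)
    behavior <- NULL
    half <- config$n_subjects >= 40
    if (half) {
      splits <- rep(c("exploratory", "validation"),
                    length.out = config$n_subjects)
      g_hat <- rep(NA_real_, config$n_subjects)
      for (idx in split(seq_len(config$n_subjects), splits)) {
        g_hat[idx] <- fit_g_scores(beh$measures[idx, , drop = FALSE])$scores
      }
      predg <- cross_sample_ridge_predict(fit_full$scores, g_hat, splits,
                                          seed = config$seed)
      behavior <- evaluate_behavior_prediction(predg, g_hat, splits)
    }

    stage <- "write"
    write_matrix(fit_full$group_matrix, file.path(out_dir, "group_latent_fc.tsv"),
                 sidecar = list(kind = "group_latent_fc", seed = config$seed))
    write_matrix(fit_full$scores, file.path(out_dir, "latent_scores.tsv"))
    write_matrix(fit_full$loadings, file.path(out_dir, "loadings.tsv"))
    write_matrix(avg, file.path(out_dir, "average_fc.tsv"))
    list(sim = sim, latent = fit_full, latent_loso = fit_loso, average = avg,
         similarity = similarity, actflow = actflow_eval, behavior = behavior)
  }, error = function(e) {
    manifest <- list(status = "failed", stage = stage, error = conditionMessage(e),
                     config = unclass(config))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    .stopf("pipeline failed at stage '%s': %s", stage, conditionMessage(e))
  })

  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  tmp <- tempfile(); writeLines(cfg_json, tmp)
  manifest <- list(status = "ok",
                   package_version = as.character(utils::packageVersion("latentfc")),
                   seed = config$seed,
                   config = unclass(config),
                   config_hash = unname(tools::md5sum(tmp)),
                   outputs = list.files(out_dir))
  unlink(tmp)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  res$manifest <- manifest
  res$out_dir <- out_dir
  invisible(res)
}
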