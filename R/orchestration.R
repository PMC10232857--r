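#' Split each client's cases into cross-validation folds
#'
#' Cases are shuffled within each client (deterministically from `seed`
#' and the client's position) and assigned round-robin, so fold sizes
#' within a client differ by at most one. Folds are stratified only
#' within client; there is no global stratification.
#'
#' @param case_ids_by_client named list of character vectors of case ids.
#' @param n_folds number of folds.
#' @param seed integer seed.
#' @return Object of class `fold_assignment`: named list (per client) of
#'   integer fold indices in `[0, n_folds)`, named by case id.
#' @export
split_folds <- function(case_ids_by_client, n_folds, seed = 1L) {
  if (!is_count(n_folds)) stopf("'n_folds' must be a positive integer")
  out <- list()
  for (ci in seq_along(case_ids_by_client)) {
    cid <- names(case_ids_by_client)[ci]
    ids <- case_ids_by_client[[ci]]
    if (length(ids) < n_folds) {
      stopf("client '%s' has %d case(s); at least %d are needed for %d folds",
            cid, length(ids), n_folds, n_folds)
    }
    shuffled <- with_seed(derive_seed(seed, 500 + ci), sample(ids))
    folds <- (seq_along(shuffled) - 1L) %% n_folds
    out[[cid]] <- stats::setNames(folds, shuffled)[ids]
  }
  structure(out, class = "fold_assignment")
}

default_experiment_config <- function() {
  list(
    network = list(in_channels = 1, depth = 2, base_channels = 4, norm = "batch"),
    federation = list(mode = "fedmsrw", n_rounds = 5, iters_per_round = 50,
                      lr = 0.05, lr_schedule = "poly", momentum = 0.9,
                      weight_decay = 5e-4, batch_size = 4,
                      patch_size = c(16, 16, 16), master_seed = 1),
    inference = list(stride = NULL, threshold = 0.5),
    cv = list(n_folds = 2, seed = 1)
  )
}

resolve_experiment_config <- function(config) {
  if (is.character(config)) config <- read_config_file(config)
  base <- default_experiment_config()
  for (sec in names(base)) {
    if (!is.null(config[[sec]])) base[[sec]] <- utils::modifyList(base[[sec]], config[[sec]])
  }
  known <- c(names(base), "data")
  bad <- setdiff(names(config), known)
  if (length(bad)) stopf("unknown config section(s): %s", paste(bad, collapse = ", "))
  if (is.null(config$data)) stopf("config must contain a 'data' section (client profiles or a NIfTI directory)")
  base$data <- config$data
  base
}

#' Run a full N-fold cross-validated federated experiment
#'
#' For each fold, a federation is trained on the remaining folds and
#' evaluated on the held-out fold of every client. The final case-level
#' Dice averages over all cases across folds; voxel-level metrics pool
#' confusion counts across all folds (per-fold reports are also kept).
#'
#' @param config a list or path to a YAML/JSON file with sections `data`
#'   (a list of client profile fields, or `nifti_dir`), `network`,
#'   `federation`, `inference` and `cv`.
#' @param out_dir optional directory for a metrics CSV and JSON history.
#' @return Object of class `experiment_result`: `overall` and `per_client`
#'   metrics reports, `per_fold` results, the `folds` assignment, and the
#'   fully resolved `config` (provenance, including the master seed).
#' @export
run_experiment <- function(config, out_dir = NULL) {
  cfg <- resolve_experiment_config(config)
  net_config <- do.call(network_config, cfg$network)
  fed_args <- cfg$federation
  if (!is.null(fed_args$patch_size)) fed_args$patch_size <- unlist(fed_args$patch_size)

  if (!is.null(cfg$data$nifti_dir)) {
    federation <- read_federation_nifti(cfg$data$nifti_dir)
  } else {
    profiles <- profiles_from_config(cfg$data)
    data_seed <- derive_seed(fed_args$master_seed %||% 1, 42)
    federation <- generate_federation(profiles, data_seed)
  }

  ids_by_client <- lapply(federation, function(cs) vapply(cs, `[[`, character(1), "case_id"))
  folds <- split_folds(ids_by_client, cfg$cv$n_folds, cfg$cv$seed)

  per_fold <- list()
  all_pred <- list(); all_truth <- list(); all_ids <- character(0)
  all_pred_by_client <- list(); all_truth_by_client <- list()
  for (f in seq_len(cfg$cv$n_folds) - 1L) {
    train_data <- list(); test_data <- list()
    for (cid in names(federation)) {
      sel <- folds[[cid]][ids_by_client[[cid]]] == f
      test_data[[cid]] <- federation[[cid]][sel]
      train_data[[cid]] <- federation[[cid]][!sel]
    }
    fa <- fed_args
    fa$master_seed <- derive_seed(fed_args$master_seed %||% 1, 900 + f)
    fed_cfg <- do.call(federation_config, fa)
    fit <- run_federation(train_data, fed_cfg, net_config)
    fold_reports <- list()
    for (cid in names(test_data)) {
      preds <- lapply(test_data[[cid]], function(case) {
        predict_case(fit$client_params[[cid]], net_config, case$volume,
                     fed_cfg$patch_size, cfg$inference$stride,
                     cfg$inference$threshold)$mask
      })
      truths <- lapply(test_data[[cid]], `[[`, "lesion_mask")
      ids <- vapply(test_data[[cid]], `[[`, character(1), "case_id")
      fold_reports[[cid]] <- evaluate_cases(preds, truths, ids)
      all_pred <- c(all_pred, preds); all_truth <- c(all_truth, truths)
      all_ids <- c(all_ids, ids)
      all_pred_by_client[[cid]] <- c(all_pred_by_client[[cid]], preds)
      all_truth_by_client[[cid]] <- c(all_truth_by_client[[cid]], truths)
    }
    per_fold[[f + 1L]] <- list(fold = f, reports = fold_reports, history = fit$history)
  }

  overall <- evaluate_cases(all_pred, all_truth, all_ids)
  per_client <- lapply(names(federation), function(cid) {
    evaluate_cases(all_pred_by_client[[cid]], all_truth_by_client[[cid]])
  })
  names(per_client) <- names(federation)

  result <- structure(list(overall = overall, per_client = per_client,
                           per_fold = per_fold, folds = folds, config = cfg),
                      class = "experiment_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_metrics_csv(c(list(overall = overall), per_client),
                      file.path(out_dir, "metrics.csv"))
    jsonlite::write_json(
      list(config = cfg,
           history = lapply(per_fold, function(pf) pf$history)),
      file.path(out_dir, "history.json"), auto_unbox = TRUE, digits = NA,
      dataframe = "rows", pretty = TRUE)
  }
  result
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result: mode '%s', %d folds, %d clients>\n",
              x$config$federation$mode, x$config$cv$n_folds, length(x$per_client)))
  cat("overall: "); print(x$overall)
  invisible(x)
}
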