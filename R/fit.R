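#' Fit a federated lesion-segmentation model
#'
#' The main user-facing entry point: trains a federation of clients on
#' their private volumetric data under the chosen aggregation strategy
#' and returns a fitted object. This is a thin modelling interface over
#' [run_federation()]; all strategy-specific behaviour (ability-weighted
#' aggregation, lesion-volume loss re-weighting, client-private
#' batch-norm state) is documented there and in the package vignette.
#'
#' @param data named list of per-client case lists, as produced by
#'   [generate_federation()] or [read_federation_nifti()].
#' @param mode federation strategy; see [federation_config()].
#' @param network a [network_config()].
#' @param control a [federation_config()]; its `mode` is overridden by
#'   `mode` when both are given.
#' @param ... convenience overrides passed to [federation_config()]
#'   (e.g. `n_rounds`, `iters_per_round`, `lr`, `patch_size`,
#'   `master_seed`).
#' @return Object of class `fedlesion`, extending `federation_result`,
#'   with `print`, `summary`, `coef`, `predict` and `plot` methods.
#' @examples
#' \donttest{
#' profiles <- list(
#'   client_profile("a", 3, volume_shape = 16, target_ratio = 0.02,
#'                  lesion_radius_range = c(1.5, 2.5), noise_sigma = 2),
#'   client_profile("b", 3, volume_shape = 16, target_ratio = 0.04,
#'                  lesion_radius_range = c(1.5, 2.5), intensity_offset = 40))
#' fed <- generate_federation(profiles, rng_seed = 7)
#' fit <- fedlesion(fed, mode = "fedmsrw", n_rounds = 2, iters_per_round = 2,
#'                  batch_size = 2, patch_size = c(16, 16, 16), lr = 0.05,
#'                  network = network_config(depth = 2, base_channels = 2))
#' fit
#' }
#' @export
fedlesion <- function(data, mode = "fedmsrw", network = network_config(),
                      control = NULL, ...) {
  dots <- list(...)
  if (is.null(control)) {
    control <- do.call(federation_config, c(list(mode = mode), dots))
  } else {
    stopifnot(inherits(control, "federation_config"))
    if (!missing(mode)) control$mode <- match.arg(mode, FED_MODES)
    if (length(dots)) control <- do.call(federation_config,
                                         utils::modifyList(unclass(control), dots))
  }
  res <- run_federation(data, control, network)
  res$call <- match.call()
  class(res) <- c("fedlesion", class(res))
  res
}

#' @export
print.fedlesion <- function(x, ...) {
  cat("Federated lesion segmentation fit\n")
  if (!is.null(x$call)) { cat("Call: "); print(x$call) }
  cat(sprintf("Mode: %s | clients: %s | %d round(s) x %d iteration(s), batch %d, patch %s\n",
              x$config$mode, paste(x$client_ids, collapse = ", "),
              x$config$n_rounds, x$config$iters_per_round, x$config$batch_size,
              paste(x$config$patch_size, collapse = "x")))
  last <- x$history[x$history$round == max(x$history$round), ]
  cat(sprintf("Final round mean Dice loss: %s\n",
              paste(sprintf("%s=%.3f", last$client, last$mean_loss), collapse = ", ")))
  invisible(x)
}

#' @export
summary.fedlesion <- function(object, ...) {
  h <- object$history
  out <- list(mode = object$config$mode, history = h,
              n_parameters = n_parameters(object$client_params[[1]]),
              client_ids = object$client_ids)
  class(out) <- "summary.fedlesion"
  out
}

#' @export
print.summary.fedlesion <- function(x, ...) {
  cat(sprintf("Federated fit summary (mode '%s', %d trainable values)\n",
              x$mode, x$n_parameters))
  cat("Per-round client trajectories (ability, aggregation weight, accumulated vr, loss):\n")
  print(x$history[, c("round", "client", "ability", "agg_weight", "vr",
                      "next_loss_weight", "mean_loss")], row.names = FALSE)
  invisible(x)
}

#' Extract fitted parameters
#'
#' @param object a fitted `fedlesion` model.
#' @param what `"client"` for the full per-client maps (default),
#'   `"global"` for the aggregated shared parameters, or `"bn"` for the
#'   per-client normalization state.
#' @param ... unused.
#' @export
coef.fedlesion <- function(object, what = c("client", "global", "bn"), ...) {
  what <- match.arg(what)
  switch(what,
         client = object$client_params,
         global = object$global_rest,
         bn = object$client_bn)
}

#' Predict lesion probabilities and masks for new volumes
#'
#' Uses the requested client's assembled model (aggregated shared
#' parameters plus that client's private normalization state) and tiled
#' patch inference with overlap averaging.
#'
#' @param object a fitted `fedlesion` model.
#' @param newdata a single case (list with `volume`), a list of cases, or
#'   a bare 3-D array.
#' @param client client id whose model to use (default: first).
#' @param patch_size,stride,threshold see [predict_case()]; the training
#'   patch size is the default.
#' @param type `"mask"` (default) or `"prob"`.
#' @param ... unused.
#' @return A single array, or a list of arrays for a list of cases.
#' @export
predict.fedlesion <- function(object, newdata, client = NULL,
                              patch_size = NULL, stride = NULL, threshold = 0.5,
                              type = c("mask", "prob"), ...) {
  type <- match.arg(type)
  if (is.null(client)) client <- object$client_ids[1]
  if (!client %in% object$client_ids) stopf("unknown client '%s'", client)
  if (is.null(patch_size)) patch_size <- object$config$patch_size
  params <- object$client_params[[client]]
  one <- function(case) {
    vol <- if (is.list(case)) case$volume else case
    predict_case(params, object$net_config, vol, patch_size, stride,
                 threshold)[[if (type == "mask") "mask" else "prob"]]
  }
  if (is.array(newdata)) return(one(newdata))
  if (is.list(newdata) && !is.null(newdata$volume)) return(one(newdata))
  lapply(newdata, one)
}

#' Plot training trajectories of a federated fit
#'
#' Draws the per-client mean Dice loss per round and, for ability-aware
#' modes, the per-client aggregation weight per round.
#'
#' @param x a fitted `fedlesion` model.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.fedlesion <- function(x, ...) {
  h <- x$history
  clients <- x$client_ids
  loss <- sapply(clients, function(cid) h$mean_loss[h$client == cid])
  wts <- sapply(clients, function(cid) h$agg_weight[h$client == cid])
  loss <- matrix(loss, ncol = length(clients))
  wts <- matrix(wts, ncol = length(clients))
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  graphics::matplot(loss, type = "b", pch = 1, lty = 1,
                    xlab = "round", ylab = "mean Dice loss",
                    main = sprintf("local training loss (%s)", x$config$mode), ...)
  graphics::legend("topright", legend = clients, col = seq_along(clients),
                   lty = 1, bty = "n")
  graphics::matplot(wts, type = "b", pch = 1, lty = 1, ylim = c(0, 1),
                    xlab = "round", ylab = "aggregation weight",
                    main = "server aggregation weights", ...)
  invisible(x)
}
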