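FED_MODES <- c("fedavg", "fedprox", "fedbn", "fedmsrw", "fedmsrw_ca_only",
               "fedmsrw_lt_only", "ours_ent", "ours_vol")

# Which modes aggregate only the shared (non-normalization) names, use
# ability-based aggregation weights, or re-weight the local loss.
mode_agg_rest_only <- function(mode) !(mode %in% c("fedavg", "fedprox"))
mode_ability_weighted <- function(mode) mode %in% c("fedmsrw", "fedmsrw_ca_only",
                                                    "ours_ent", "ours_vol")
mode_loss_reweighted <- function(mode) mode %in% c("fedmsrw", "fedmsrw_lt_only",
                                                   "ours_vol")

#' Configure a federated training run
#'
#' Defaults follow the reference training protocol: SGD with momentum
#' 0.9, weight decay 5e-4 and learning rate 2e-4, with aggregation after
#' every 800 local iterations. Desk-scale experiments typically shrink
#' `iters_per_round` and `patch_size` and raise `lr` accordingly.
#'
#' @param mode one of `"fedavg"`, `"fedprox"`, `"fedbn"`, `"fedmsrw"`
#'   (ability-weighted aggregation + lesion-volume loss re-weighting),
#'   the two single-component ablations `"fedmsrw_ca_only"` /
#'   `"fedmsrw_lt_only"`, and the `"ours_ent"` / `"ours_vol"` variants.
#' @param n_rounds number of federation rounds P.
#' @param iters_per_round local SGD iterations Q per round (default 800).
#' @param lr,momentum,weight_decay SGD hyper-parameters.
#' @param prox_mu proximal coefficient (fedprox only).
#' @param lr_schedule `"constant"` (the reference protocol) or `"poly"`,
#'   which decays the round-`p` learning rate as
#'   `lr * (1 - (p-1)/n_rounds)^lr_power`. Short desk-scale runs benefit
#'   from starting high and annealing.
#' @param lr_power exponent of the polynomial decay.
#' @param batch_size training patches per iteration.
#' @param patch_size integer triple of the training patch.
#' @param master_seed integer seed controlling every random draw of the
#'   run (patch sampling, augmentation, initialization).
#' @param augment apply random flip/rotation augmentation.
#' @param vr_eps floor applied to a client's ratio in the loss-weight
#'   denominator.
#' @param vr_clip two-sided clip on the loss weight.
#' @param ability_override if set, every client reports this ability
#'   (diagnostic; makes ability-weighted aggregation uniform).
#' @param loss_weight_override if set, every client trains with this
#'   fixed loss weight (diagnostic).
#' @return Object of class `federation_config`.
#' @export
federation_config <- function(mode = "fedmsrw",
                              n_rounds = 5L,
                              iters_per_round = 800L,
                              lr = 2e-4,
                              lr_schedule = c("constant", "poly"),
                              lr_power = 1,
                              momentum = 0.9,
                              weight_decay = 5e-4,
                              prox_mu = 1e-3,
                              batch_size = 4L,
                              patch_size = c(64L, 64L, 64L),
                              master_seed = 1L,
                              augment = TRUE,
                              vr_eps = 1e-6,
                              vr_clip = c(0.1, 10),
                              ability_override = NULL,
                              loss_weight_override = NULL) {
  mode <- match.arg(mode, FED_MODES)
  lr_schedule <- match.arg(lr_schedule)
  if (!is_count(n_rounds)) stopf("'n_rounds' must be a positive integer")
  if (!is_count(iters_per_round)) stopf("'iters_per_round' must be a positive integer")
  if (!is_count(batch_size)) stopf("'batch_size' must be a positive integer")
  if (lr < 0 || momentum < 0 || weight_decay < 0 || prox_mu < 0) {
    stopf("rates must be nonnegative")
  }
  structure(list(mode = mode, n_rounds = as.integer(n_rounds),
                 iters_per_round = as.integer(iters_per_round),
                 lr = lr, lr_schedule = lr_schedule, lr_power = lr_power,
                 momentum = momentum, weight_decay = weight_decay,
                 prox_mu = prox_mu, batch_size = as.integer(batch_size),
                 patch_size = check_triple(patch_size, "patch_size"),
                 master_seed = as.integer(master_seed), augment = augment,
                 vr_eps = vr_eps, vr_clip = vr_clip,
                 ability_override = ability_override,
                 loss_weight_override = loss_weight_override),
            class = "federation_config")
}

#' Lesion-volume loss re-weighting factor
#'
#' For client `i` among `N` clients with accumulated lesion-volume ratios
#' `vr`, the factor is `sum(vr) / (N * vr[i])`: clients whose training
#' data carry proportionally smaller lesions train with a larger soft
#' Dice loss. The denominator is floored at `eps` and the result clipped
#' to `clip` to guard against near-lesion-free clients. When no clipping
#' triggers, `sum(w * vr) == sum(vr)`.
#'
#' @param all_vr numeric vector of every client's accumulated ratio.
#' @param i client index.
#' @param eps denominator floor (default 1e-6).
#' @param clip length-2 clipping interval (default `c(0.1, 10)`).
#' @return Positive scalar weight.
#' @examples
#' loss_weight(c(0.01, 0.03), 1)  # 2
#' loss_weight(c(0.01, 0.03), 2)  # 0.667
#' @export
loss_weight <- function(all_vr, i, eps = 1e-6, clip = c(0.1, 10)) {
  if (length(all_vr) == 0) stopf("'all_vr' must not be empty")
  if (any(all_vr < 0)) stopf("lesion-volume ratios must be nonnegative")
  if (i < 1 || i > length(all_vr)) stopf("client index out of range")
  w <- sum(all_vr) / (length(all_vr) * max(all_vr[i], eps))
  min(max(w, clip[1]), clip[2])
}

# Shared weighted sum over named parameter maps.
weighted_param_sum <- function(param_sets, weights, names) {
  out <- vector("list", length(names))
  names(out) <- names
  for (nm in names) {
    ref <- param_sets[[1]][[nm]]
    if (is.null(ref)) stopf("client 1 is missing parameter '%s'", nm)
    ref_shape <- dim(ref) %||% length(ref)
    acc <- ref * weights[1]
    for (k in seq_along(param_sets)[-1]) {
      v <- param_sets[[k]][[nm]]
      if (is.null(v)) stopf("client %d is missing parameter '%s'", k, nm)
      v_shape <- dim(v) %||% length(v)
      if (length(v_shape) != length(ref_shape) || any(v_shape != ref_shape)) {
        stopf("shape mismatch across clients for parameter '%s'", nm)
      }
      acc <- acc + v * weights[k]
    }
    out[[nm]] <- acc
  }
  out
}

#' Uniform (FedAvg/FedBN) aggregation of named parameter maps
#'
#' Arithmetic mean per entry over the selected names; entries outside
#' `names` are not returned (they remain client-local).
#'
#' @param param_sets list of N named parameter lists.
#' @param names character vector of names to aggregate.
#' @return Named list over `names`.
#' @export
average_aggregate <- function(param_sets, names) {
  n <- length(param_sets)
  if (n < 1) stopf("need at least one parameter set")
  weighted_param_sum(param_sets, rep(1 / n, n), names)
}

#' Ability-weighted aggregation of named parameter maps
#'
#' Per entry, `sum_i theta_i * P_i / sum_i P_i` over the selected names.
#' With equal abilities this reduces (bitwise) to [average_aggregate()].
#'
#' @param param_sets list of N named parameter lists.
#' @param abilities nonnegative per-client ability scores; at least one
#'   must be positive.
#' @param names character vector of names to aggregate.
#' @return Named list over `names`.
#' @export
weighted_aggregate <- function(param_sets, abilities, names) {
  n <- length(param_sets)
  if (length(abilities) != n) stopf("need one ability per parameter set")
  if (any(abilities < 0)) stopf("abilities must be nonnegative")
  if (all(abilities == 0)) {
    stopf(paste("all abilities are zero; substitute a uniform ability",
                "(e.g. 0.5) for every client before aggregating"))
  }
  w <- if (length(unique(abilities)) == 1) rep(1 / n, n) else abilities / sum(abilities)
  weighted_param_sum(param_sets, w, names)
}

sgd_update <- function(params, grads, opt_state, lr, momentum, weight_decay,
                       trainable) {
  for (nm in trainable) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (weight_decay > 0) g <- g + weight_decay * params[[nm]]
    v <- opt_state[[nm]]
    v <- if (is.null(v) || momentum == 0) g else momentum * v + g
    opt_state[[nm]] <- v
    params[[nm]] <- params[[nm]] - lr * v
  }
  list(params = params, opt_state = opt_state)
}

#' Run one local training round on a client
#'
#' Performs `Q = config$iters_per_round` SGD iterations on randomly
#' sampled (optionally augmented) patches, minimizing
#' `global_loss_weight * soft Dice loss` (plus, in fedprox mode,
#' `prox_mu/2 * ||theta - theta_start||^2` over the trainable
#' parameters). Per iteration and per patch it records an ability
#' observation (absent when the patch holds no lesion voxels), the
#' lesion-volume ratio, and the lesion voxel count.
#'
#' @param cases list of training cases for this client.
#' @param params full named parameter map to start from.
#' @param config a [federation_config()].
#' @param net_config the [network_config()].
#' @param global_loss_weight scalar multiplying the Dice loss.
#' @param opt_state momentum buffers carried across rounds (client-local,
#'   never transmitted); `NULL` to start from zero.
#' @param rng_seed seed for this round's sampling.
#' @param prox_reference parameter map the proximal term pulls towards
#'   (fedprox mode only; defaults to `params`).
#' @return List with updated `params`, `opt_state`, `round_ability`
#'   (mean of present observations, `NA` if none), `n_present`,
#'   `round_mean_ratio`, `round_mean_voxels`, `round_mean_entropy_ability`
#'   and `mean_loss`.
#' @export
local_train_round <- function(cases, params, config, net_config,
                              global_loss_weight = 1, opt_state = NULL,
                              rng_seed = 1L, prox_reference = NULL) {
  if (length(cases) == 0) stopf("client has no training cases")
  if (config$iters_per_round < 1) stopf("iters_per_round must be >= 1")
  part <- partition_parameters(params)
  trainable <- setdiff(names(params), grep("running_(mean|var)$", names(params), value = TRUE))
  if (is.null(opt_state)) opt_state <- list()
  if (is.null(prox_reference)) prox_reference <- params
  use_prox <- config$mode == "fedprox" && config$prox_mu > 0
  abilities <- numeric(0)
  ent_abilities <- numeric(0)
  ratios <- numeric(0)
  voxels <- numeric(0)
  losses <- numeric(config$iters_per_round)
  B <- config$batch_size
  ps <- config$patch_size
  with_seed(rng_seed, {
    for (it in seq_len(config$iters_per_round)) {
      idx <- sample.int(length(cases), B, replace = TRUE)
      vols <- array(0, dim = c(ps, 1L, B))
      msks <- array(0, dim = c(ps, 1L, B))
      for (b in seq_len(B)) {
        pt <- sample_patch(cases[[idx[b]]], ps, augment = config$augment)
        vols[, , , 1L, b] <- pt$volume
        msks[, , , 1L, b] <- pt$mask
        ratios <- c(ratios, lesion_volume_ratio(pt$volume, pt$mask))
        voxels <- c(voxels, sum(pt$mask != 0))
      }
      fw <- fednet_forward(params, net_config, vols, train = TRUE, with_tape = TRUE)
      params[names(fw$buffers)] <- fw$buffers
      prob5 <- fw$tape$prob5
      dprob <- array(0, dim = dim(prob5))
      loss_it <- 0
      for (b in seq_len(B)) {
        pb <- prob5[, , , 1L, b]
        yb <- msks[, , , 1L, b]
        lb <- soft_dice_loss(pb, yb)
        loss_it <- loss_it + lb / B
        dprob[, , , 1L, b] <- soft_dice_grad(pb, yb) * (global_loss_weight / B)
        ab <- segmentation_ability(pb, yb)
        if (!ab$absent) abilities <- c(abilities, ab$value)
        ent_abilities <- c(ent_abilities, entropy_ability(pb, yb))
      }
      if (!is.finite(loss_it)) stopf("non-finite loss at iteration %d", it)
      losses[it] <- global_loss_weight * loss_it
      grads <- fednet_backward(params, fw$tape, dprob)
      if (use_prox) {
        for (nm in trainable) {
          grads[[nm]] <- (grads[[nm]] %||% 0) +
            config$prox_mu * (params[[nm]] - prox_reference[[nm]])
        }
      }
      upd <- sgd_update(params, grads, opt_state, config$lr, config$momentum,
                        config$weight_decay, trainable)
      params <- upd$params
      opt_state <- upd$opt_state
    }
  })
  list(params = params, opt_state = opt_state,
       round_ability = if (length(abilities)) mean(abilities) else NA_real_,
       n_present = length(abilities),
       round_mean_ratio = mean(ratios),
       round_mean_voxels = mean(voxels),
       round_mean_entropy_ability = mean(ent_abilities),
       mean_loss = mean(losses))
}

#' Run a full federated training loop
#'
#' Implements the round structure: every client is initialized from the
#' global model (all parameters in fedavg/fedprox; only the shared
#' non-normalization parameters in fedbn/fedmsrw-family modes, keeping
#' batch-norm state client-private), trains locally for Q iterations with
#' its mode-specific loss weight, then the server aggregates -- uniformly,
#' or weighted by the clients' round abilities -- and redistributes.
#' Loss re-weighting factors are computed from the clients' accumulated
#' lesion-volume ratios *after* each aggregation, so round 1 always
#' trains with unit weights. Only scalar summaries (ability, ratio) and
#' model parameters ever travel between client and server.
#'
#' @param federation named list (by client id) of lists of cases, as from
#'   [generate_federation()].
#' @param config a [federation_config()].
#' @param net_config a [network_config()].
#' @return Object of class `federation_result`: list with `client_params`
#'   (full per-client maps), `global_rest`, `client_bn`, `partition`,
#'   `history` (per-round data frame), `client_states`, `config`,
#'   `net_config` and `client_ids`.
#' @export
run_federation <- function(federation, config, net_config = network_config()) {
  stopifnot(inherits(config, "federation_config"))
  if (length(federation) < 2) stopf("a federation needs at least 2 clients")
  if (is.null(names(federation)) || anyDuplicated(names(federation))) {
    stopf("federation must be a named list with unique client ids")
  }
  for (cid in names(federation)) {
    if (length(federation[[cid]]) == 0) stopf("client '%s' has no training cases", cid)
  }
  # fixed aggregation order for reproducible floating-point summation
  client_ids <- sort(names(federation))
  n <- length(client_ids)
  mode <- config$mode

  net <- build_network(net_config, derive_seed(config$master_seed, 1))
  partition <- partition_parameters(net)
  agg_names <- if (mode_agg_rest_only(mode)) partition$rest_names else names(net$params)

  client_params <- stats::setNames(lapply(client_ids, function(i) net$params), client_ids)
  opt_states <- stats::setNames(vector("list", n), client_ids)
  states <- stats::setNames(lapply(client_ids, function(i) client_state()), client_ids)
  loss_weights <- stats::setNames(rep(1, n), client_ids)  # round 1: unit weights
  global_agg <- NULL
  history <- list()

  for (p in seq_len(config$n_rounds)) {
    round_cfg <- config
    if (config$lr_schedule == "poly") {
      round_cfg$lr <- config$lr * (1 - (p - 1) / config$n_rounds)^config$lr_power
    }
    round_ab <- stats::setNames(rep(NA_real_, n), client_ids)
    round_ent <- stats::setNames(rep(NA_real_, n), client_ids)
    round_loss <- stats::setNames(rep(NA_real_, n), client_ids)
    for (ci in seq_along(client_ids)) {
      cid <- client_ids[ci]
      params <- client_params[[cid]]
      if (!is.null(global_agg)) {
        params[names(global_agg)] <- global_agg  # bn names stay client-local
      }
      prox_ref <- params
      lw <- if (!is.null(config$loss_weight_override)) {
        config$loss_weight_override
      } else if (mode_loss_reweighted(mode)) loss_weights[[cid]] else 1
      res <- local_train_round(federation[[cid]], params, round_cfg, net_config,
                               global_loss_weight = lw,
                               opt_state = opt_states[[cid]],
                               rng_seed = derive_seed(config$master_seed, p, ci),
                               prox_reference = prox_ref)
      client_params[[cid]] <- res$params
      opt_states[[cid]] <- res$opt_state
      states[[cid]] <- update_running_ratio(states[[cid]], res$round_mean_ratio,
                                            res$round_mean_voxels)
      states[[cid]]$round_ability <- res$round_ability
      round_ab[cid] <- res$round_ability
      round_ent[cid] <- res$round_mean_entropy_ability
      round_loss[cid] <- res$mean_loss
    }

    # server-side aggregation
    abilities_raw <- if (mode == "ours_ent") round_ent else round_ab
    abilities <- abilities_raw
    if (!is.null(config$ability_override)) {
      abilities[] <- config$ability_override
    } else {
      present <- !is.na(abilities)
      fill <- if (any(present)) mean(abilities[present]) else 0.5
      abilities[!present] <- fill
    }
    if (mode_ability_weighted(mode)) {
      if (all(abilities == 0)) abilities[] <- 0.5
      agg_w <- if (length(unique(abilities)) == 1) rep(1 / n, n) else abilities / sum(abilities)
      global_agg <- weighted_aggregate(client_params[client_ids], abilities, agg_names)
    } else {
      agg_w <- rep(1 / n, n)
      global_agg <- average_aggregate(client_params[client_ids], agg_names)
    }

    # next round's loss re-weighting factors from the accumulated ratios
    vr_now <- vapply(client_ids, function(cid) states[[cid]]$vr, numeric(1))
    v_now <- vapply(client_ids, function(cid) states[[cid]]$v_voxels, numeric(1))
    basis <- if (mode == "ours_vol") v_now else vr_now
    loss_weights <- stats::setNames(vapply(seq_len(n), function(i) {
      loss_weight(basis, i, eps = config$vr_eps, clip = config$vr_clip)
    }, numeric(1)), client_ids)

    history[[p]] <- data.frame(
      round = p, client = client_ids,
      ability_raw = unname(abilities_raw), ability = unname(abilities),
      agg_weight = agg_w, vr = unname(vr_now), v_voxels = unname(v_now),
      next_loss_weight = unname(loss_weights),
      mean_loss = unname(round_loss), stringsAsFactors = FALSE)
  }

  # final per-client models: aggregated shared weights + private bn state
  client_bn <- lapply(client_params[client_ids], function(p) p[partition$bn_names])
  if (mode_agg_rest_only(mode)) {
    global_rest <- global_agg
    final <- lapply(client_ids, function(cid) {
      assemble_client_parameters(global_rest, client_bn[[cid]], partition)
    })
  } else {
    global_rest <- global_agg[partition$rest_names]
    final <- lapply(client_ids, function(cid) global_agg[names(net$params)])
    client_bn <- lapply(client_ids, function(cid) global_agg[partition$bn_names])
    names(client_bn) <- client_ids
  }
  names(final) <- client_ids

  structure(list(client_params = final, global_rest = global_rest,
                 client_bn = client_bn, partition = partition,
                 history = do.call(rbind, history), client_states = states,
                 config = config, net_config = net_config,
                 client_ids = client_ids),
            class = "federation_result")
}

#' @export
print.federation_result <- function(x, ...) {
  cat(sprintf("<federation_result: mode '%s', %d clients, %d rounds x %d iterations>\n",
              x$config$mode, length(x$client_ids), x$config$n_rounds,
              x$config$iters_per_round))
  last <- x$history[x$history$round == max(x$history$round), ]
  cat("  final round:\n")
  print(last[, c("client", "ability", "agg_weight", "vr", "next_loss_weight", "mean_loss")],
        row.names = FALSE)
  invisible(x)
}
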