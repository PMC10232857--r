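#' Soft Dice loss for probabilistic binary segmentation
#'
#' Computes `1 - (2*sum(p*y) + eps) / (sum(p^2) + sum(y^2) + eps)` over
#' all voxels. The smoothing constant `eps` appears in both numerator and
#' denominator so that a perfect binary prediction scores exactly 0 and
#' an empty prediction of an empty target scores 0 rather than being
#' undefined.
#'
#' @param pred numeric array of probabilities in \[0, 1\].
#' @param target binary array (0/1) of identical shape.
#' @param eps smoothing constant (default 1e-5).
#' @return Loss in \[0, 1\].
#' @examples
#' soft_dice_loss(array(0.5, c(2, 2, 2)), array(c(1, 1, 1, 1, 0, 0, 0, 0), c(2, 2, 2)))
#' @export
soft_dice_loss <- function(pred, target, eps = 1e-5) {
  check_same_shape(pred, target, "pred and target")
  p <- as.numeric(pred); y <- as.numeric(target)
  1 - (2 * sum(p * y) + eps) / (sum(p * p) + sum(y * y) + eps)
}

# Gradient of the soft Dice loss with respect to pred.
soft_dice_grad <- function(pred, target, eps = 1e-5) {
  p <- as.numeric(pred); y <- as.numeric(target)
  num <- 2 * sum(p * y) + eps
  den <- sum(p * p) + sum(y * y) + eps
  g <- (2 * num * p - 2 * den * y) / den^2
  dim(g) <- dim(pred)
  g
}

#' Segmentation ability of a model on one labelled patch
#'
#' The ability score weighs a model's confidence inside the true lesion
#' (mean predicted probability over lesion voxels) by its segmentation
#' accuracy `(1 - soft Dice loss)`. It is undefined when the ground-truth
#' patch contains no lesion voxels; in that case an *absent* observation
#' is returned (reason `"empty_ground_truth"`) and the federation layer
#' substitutes the mean ability of the reporting clients.
#'
#' @inheritParams soft_dice_loss
#' @return An `ability_observation`: list with `value` (in \[0, 1\] or
#'   `NA`), `absent` flag and `reason_absent`.
#' @export
segmentation_ability <- function(pred, target) {
  check_same_shape(pred, target, "pred and target")
  sy <- sum(target)
  if (sy == 0) {
    return(structure(list(value = NA_real_, absent = TRUE,
                          reason_absent = "empty_ground_truth"),
                     class = "ability_observation"))
  }
  confidence <- sum(as.numeric(pred) * as.numeric(target)) / sy
  structure(list(value = confidence * (1 - soft_dice_loss(pred, target)),
                 absent = FALSE, reason_absent = NA_character_),
            class = "ability_observation")
}

#' @export
print.ability_observation <- function(x, ...) {
  if (x$absent) cat(sprintf("<ability: absent (%s)>\n", x$reason_absent))
  else cat(sprintf("<ability: %.4f>\n", x$value))
  invisible(x)
}

#' Entropy-based ability score (whole-map uncertainty variant)
#'
#' Replaces the in-lesion confidence with the mean voxelwise prediction
#' entropy `-p*log(p)` (natural log, with `0*log(0) := 0`), scaled by
#' `(1 - soft Dice loss)`. Always defined, including on lesion-free
#' patches. Used by the `ours_ent` federation mode.
#'
#' @inheritParams soft_dice_loss
#' @return Nonnegative scalar.
#' @export
entropy_ability <- function(pred, target) {
  check_same_shape(pred, target, "pred and target")
  p <- as.numeric(pred)
  h <- ifelse(p > 0, -p * log(p), 0)
  mean(h) * (1 - soft_dice_loss(pred, target))
}

#' Lesion-volume ratio of a patch
#'
#' Ratio of lesion voxels to brain voxels, where brain voxels are those
#' with nonzero intensity (background is exactly zero in brain-extracted
#' input). Returns 0 for an all-background patch.
#'
#' @param volume intensity patch.
#' @param mask binary lesion patch of identical shape.
#' @return Ratio in \[0, 1\].
#' @export
lesion_volume_ratio <- function(volume, mask) {
  check_same_shape(volume, mask, "volume and mask")
  brain <- sum(volume != 0)
  if (brain == 0) return(0)
  min(sum(mask != 0) / brain, 1)
}

#' Per-client running state of the federation
#'
#' Tracks the running mean lesion-volume ratio `vr` across rounds (the
#' accumulated estimate used by the loss re-weighting), a parallel
#' running mean of lesion voxel counts (used by the `ours_vol` ablation),
#' the round counter, and the last round's mean ability.
#'
#' @param vr initial running ratio.
#' @param rounds_seen rounds already accumulated.
#' @return Object of class `client_state`.
#' @export
client_state <- function(vr = 0, rounds_seen = 0L) {
  structure(list(vr = vr, rounds_seen = as.integer(rounds_seen),
                 round_ability = NA_real_, v_voxels = 0),
            class = "client_state")
}

#' Accumulate a round's mean lesion-volume ratio into the running mean
#'
#' After `k` rounds the running value equals the arithmetic mean of the
#' `k` round means: `vr <- ((k-1)*vr + round_mean) / k`.
#'
#' @param state a [client_state()].
#' @param round_mean this round's mean ratio, in \[0, 1\].
#' @param round_mean_voxels optional round mean lesion voxel count, kept
#'   as a parallel running mean.
#' @return Updated `client_state`.
#' @export
update_running_ratio <- function(state, round_mean, round_mean_voxels = NULL) {
  stopifnot(inherits(state, "client_state"))
  if (!is.finite(round_mean) || round_mean < 0) {
    stopf("round_mean must be a nonnegative finite number")
  }
  if (round_mean > 1) stopf("round_mean is a ratio and cannot exceed 1")
  k <- state$rounds_seen + 1L
  state$vr <- ((k - 1) * state$vr + round_mean) / k
  if (!is.null(round_mean_voxels)) {
    if (round_mean_voxels < 0) stopf("round_mean_voxels must be nonnegative")
    state$v_voxels <- ((k - 1) * state$v_voxels + round_mean_voxels) / k
  }
  state$rounds_seen <- k
  state
}

#' Voxel confusion counts between a predicted and a true mask
#'
#' @param pred_mask,truth_mask binary arrays of identical shape.
#' @return Object of class `confusion_counts` with `tp`, `fp`, `fn`.
#' @export
confusion_counts <- function(pred_mask, truth_mask) {
  check_same_shape(pred_mask, truth_mask, "masks")
  p <- as.logical(pred_mask); y <- as.logical(truth_mask)
  structure(list(tp = sum(p & y), fp = sum(p & !y), fn = sum(!p & y)),
            class = "confusion_counts")
}

#' Dice, TPR and FPR from voxel confusion counts
#'
#' `dice = 2*TP / (FN + 2*TP + FP)`, `tpr = TP / (TP + FN)` and
#' `fpr = FP / (TP + FP)`. Note that this "FPR" is the fraction of
#' positive predictions that are wrong (conventionally the false
#' discovery rate); it is implemented in this form deliberately, as this
#' is the quantity the evaluation protocol reports. Zero-denominator
#' conventions: dice is 1 when TP = FP = FN = 0, tpr is 1 when
#' TP + FN = 0, fpr is 0 when TP + FP = 0.
#'
#' @param counts a [confusion_counts()] or list with `tp`, `fp`, `fn`.
#' @return Named numeric vector `(dice, tpr, fpr)` in \[0, 1\].
#' @examples
#' volume_metrics(list(tp = 10, fp = 5, fn = 5))
#' @export
volume_metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
  if (any(c(tp, fp, fn) < 0)) stopf("confusion counts must be nonnegative")
  dice <- if (tp + fp + fn == 0) 1 else 2 * tp / (fn + 2 * tp + fp)
  tpr <- if (tp + fn == 0) 1 else tp / (tp + fn)
  fpr <- if (tp + fp == 0) 0 else fp / (tp + fp)
  c(dice = dice, tpr = tpr, fpr = fpr)
}

#' Case-level and voxel-level segmentation metrics
#'
#' C-Dice is the mean of per-case Dice scores; the voxel-level metrics
#' (V-Dice, V-TPR, V-FPR) are computed from TP/FP/FN counts pooled over
#' the voxels of all cases. All four are reported in percent.
#'
#' @param pred_masks list of predicted binary masks.
#' @param truth_masks list of ground-truth binary masks, same length and
#'   per-case shapes.
#' @param case_ids optional case identifiers.
#' @return Object of class `metrics_report`: list with `c_dice`,
#'   `v_dice`, `v_tpr`, `v_fpr` (percent), pooled `counts`, and a
#'   `per_case` data frame.
#' @export
evaluate_cases <- function(pred_masks, truth_masks, case_ids = NULL) {
  n <- length(pred_masks)
  if (n < 1 || length(truth_masks) != n) {
    stopf("need >= 1 case and equally many predictions and ground truths")
  }
  if (is.null(case_ids)) case_ids <- sprintf("case%03d", seq_len(n))
  tp <- fp <- fn <- 0
  per_dice <- numeric(n)
  for (i in seq_len(n)) {
    dp <- dim(pred_masks[[i]]); dt <- dim(truth_masks[[i]])
    if (length(dp) != length(dt) || any(dp != dt)) {
      stopf("case '%s': prediction shape %s does not match ground truth %s",
            case_ids[i], paste(dp, collapse = "x"), paste(dt, collapse = "x"))
    }
    cc <- confusion_counts(pred_masks[[i]], truth_masks[[i]])
    per_dice[i] <- volume_metrics(cc)[["dice"]]
    tp <- tp + cc$tp; fp <- fp + cc$fp; fn <- fn + cc$fn
  }
  vm <- volume_metrics(list(tp = tp, fp = fp, fn = fn))
  structure(list(
    c_dice = 100 * mean(per_dice),
    v_dice = 100 * vm[["dice"]],
    v_tpr = 100 * vm[["tpr"]],
    v_fpr = 100 * vm[["fpr"]],
    counts = list(tp = tp, fp = fp, fn = fn),
    per_case = data.frame(case_id = case_ids, dice = 100 * per_dice,
                          stringsAsFactors = FALSE)
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report over %d case(s)>\n", nrow(x$per_case)))
  cat(sprintf("  C-Dice %6.2f  V-Dice %6.2f  V-TPR %6.2f  V-FPR %6.2f  (percent)\n",
              x$c_dice, x$v_dice, x$v_tpr, x$v_fpr))
  invisible(x)
}

#' @export
as.data.frame.metrics_report <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(c_dice = x$c_dice, v_dice = x$v_dice, v_tpr = x$v_tpr,
             v_fpr = x$v_fpr, row.names = row.names)
}

#' Write one or more metrics reports as a CSV table
#'
#' One row per report, columns `(client, C-Dice, V-Dice, V-TPR, V-FPR)`.
#'
#' @param reports a `metrics_report` or named list of them.
#' @param path output CSV path.
#' @export
write_metrics_csv <- function(reports, path) {
  if (inherits(reports, "metrics_report")) reports <- list(overall = reports)
  df <- do.call(rbind, lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    data.frame(client = nm, `C-Dice` = r$c_dice, `V-Dice` = r$v_dice,
               `V-TPR` = r$v_tpr, `V-FPR` = r$v_fpr, check.names = FALSE)
  }))
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}
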