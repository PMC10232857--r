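#' Plan a complete patch tiling of a volume
#'
#' Offsets are placed at multiples of `stride` on every axis, with a
#' final offset clamped to `volume_shape - patch_size` so every voxel is
#' covered; duplicate offsets are dropped.
#'
#' @param volume_shape integer triple.
#' @param patch_size integer triple, each at most the volume shape.
#' @param stride integer triple (or scalar) in `[1, patch_size]`.
#' @return Object of class `tiling_plan`: list with an `offsets` matrix
#'   (one row per patch, 0-based), `patch_size` and `volume_shape`.
#' @examples
#' tile_volume(c(48, 48, 48), c(32, 32, 32), 16)$offsets
#' @export
tile_volume <- function(volume_shape, patch_size, stride) {
  volume_shape <- check_triple(volume_shape, "volume_shape")
  patch_size <- check_triple(patch_size, "patch_size")
  stride <- check_triple(stride, "stride")
  if (any(patch_size > volume_shape)) {
    stopf("patch_size %s exceeds volume shape %s",
          paste(patch_size, collapse = "x"), paste(volume_shape, collapse = "x"))
  }
  if (any(stride > patch_size)) stopf("stride must not exceed patch_size")
  axis_offsets <- lapply(1:3, function(ax) {
    last <- volume_shape[ax] - patch_size[ax]
    unique(c(seq(0L, last, by = stride[ax]), last))
  })
  grid <- expand.grid(axis_offsets[[1]], axis_offsets[[2]], axis_offsets[[3]],
                      KEEP.OUT.ATTRS = FALSE)
  structure(list(offsets = unname(as.matrix(grid)), patch_size = patch_size,
                 volume_shape = volume_shape),
            class = "tiling_plan")
}

#' @export
print.tiling_plan <- function(x, ...) {
  cat(sprintf("<tiling_plan: %d patches of %s over %s>\n", nrow(x$offsets),
              paste(x$patch_size, collapse = "x"),
              paste(x$volume_shape, collapse = "x")))
  invisible(x)
}

#' Predict a whole volume by tiled patch inference
#'
#' Tiles the volume, runs the network in evaluation mode (stored running
#' statistics, no updates) on each patch, and averages probabilities over
#' all patches covering each voxel. Volumes smaller than the patch on any
#' axis are zero-padded and cropped back. The default stride of half the
#' patch gives overlap-averaged, seam-robust predictions; `stride =
#' patch_size` reproduces exact non-overlapping tiling.
#'
#' @param params full named parameter map of the model.
#' @param net_config the [network_config()].
#' @param volume 3-D intensity array (or 4-D with a channel axis).
#' @param patch_size integer triple.
#' @param stride integer triple or scalar; default `patch_size / 2`.
#' @param threshold probability threshold for the binary mask.
#' @return List with `prob` (probability volume) and `mask` (binary
#'   integer volume).
#' @export
predict_case <- function(params, net_config, volume, patch_size,
                         stride = NULL, threshold = 0.5) {
  patch_size <- check_triple(patch_size, "patch_size")
  if (is.null(stride)) stride <- pmax(patch_size %/% 2L, 1L)
  stride <- check_triple(stride, "stride")
  d <- dim(volume)
  multi <- length(d) == 4
  spatial <- d[1:3]
  pad <- pmax(patch_size - spatial, 0L)
  if (any(pad > 0)) {
    padded_shape <- spatial + pad
    pv <- array(0, dim = c(padded_shape, if (multi) d[4] else NULL))
    if (multi) pv[seq_len(spatial[1]), seq_len(spatial[2]), seq_len(spatial[3]), ] <- volume
    else pv[seq_len(spatial[1]), seq_len(spatial[2]), seq_len(spatial[3])] <- volume
    volume <- pv
    spatial <- padded_shape
  }
  plan <- tile_volume(spatial, patch_size, stride)
  prob_sum <- array(0, dim = spatial)
  cover <- array(0, dim = spatial)
  for (r in seq_len(nrow(plan$offsets))) {
    off <- plan$offsets[r, ]
    i1 <- off[1] + seq_len(patch_size[1])
    i2 <- off[2] + seq_len(patch_size[2])
    i3 <- off[3] + seq_len(patch_size[3])
    patch <- if (multi) volume[i1, i2, i3, , drop = FALSE] else volume[i1, i2, i3, drop = FALSE]
    fw <- fednet_forward(params, net_config, patch, train = FALSE)
    p <- array(fw$prob, dim = patch_size)
    if (any(!is.finite(p))) stopf("non-finite prediction in patch at offset (%s)",
                                  paste(off, collapse = ", "))
    prob_sum[i1, i2, i3] <- prob_sum[i1, i2, i3] + p
    cover[i1, i2, i3] <- cover[i1, i2, i3] + 1
  }
  prob <- prob_sum / cover
  orig <- d[1:3]
  prob <- prob[seq_len(orig[1]), seq_len(orig[2]), seq_len(orig[3]), drop = FALSE]
  dim(prob) <- orig
  list(prob = prob, mask = array(as.integer(prob >= threshold), dim = orig))
}

#' Evaluate one client's assembled model on its cases
#'
#' Builds the client model from the globally aggregated shared parameters
#' and the client's private normalization parameters, predicts every case
#' by tiled inference, and scores the predictions.
#'
#' @param cases list of cases (each with `volume` and `lesion_mask`).
#' @param global_rest named shared parameter values.
#' @param client_bn named client-local normalization values.
#' @param net_config the [network_config()].
#' @param partition the [partition_parameters()] result.
#' @param patch_size,stride,threshold passed to [predict_case()].
#' @return A [evaluate_cases()] `metrics_report`.
#' @export
evaluate_client <- function(cases, global_rest, client_bn, net_config, partition,
                            patch_size, stride = NULL, threshold = 0.5) {
  params <- assemble_client_parameters(global_rest, client_bn, partition)
  preds <- lapply(cases, function(case) {
    predict_case(params, net_config, case$volume, patch_size, stride, threshold)$mask
  })
  evaluate_cases(preds, lapply(cases, `[[`, "lesion_mask"),
                 vapply(cases, `[[`, character(1), "case_id"))
}
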