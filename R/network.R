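#' Configure the 3-D encoder--decoder segmentation network
#'
#' The network is a compact 3-D U-Net: `depth` levels of two 3x3x3
#' convolutions (each followed by batch normalization and ReLU) with 2x
#' max pooling between levels, a bottleneck block, a mirrored decoder
#' with nearest-neighbour upsampling and skip concatenation, and a final
#' 1x1x1 convolution with a sigmoid yielding voxelwise lesion
#' probabilities in \[0, 1\].
#'
#' @param in_channels number of input channels (default 1, FLAIR-like).
#' @param depth number of pooling levels, >= 1. Input patch axes must be
#'   divisible by `2^depth`.
#' @param base_channels channels at the first level; doubled per level.
#' @param norm `"batch"` (default) or `"none"`.
#' @return An object of class `network_config`.
#' @export
network_config <- function(in_channels = 1L, depth = 3L, base_channels = 8L,
                           norm = c("batch", "none")) {
  norm <- match.arg(norm)
  if (!is_count(in_channels) || !is_count(depth) || !is_count(base_channels)) {
    stopf("in_channels, depth and base_channels must be positive integers")
  }
  structure(list(in_channels = as.integer(in_channels), depth = as.integer(depth),
                 base_channels = as.integer(base_channels), norm = norm),
            class = "network_config")
}

# Ordered table of every convolution in the network: block name, conv
# index within the block, input/output channels, kernel size, and whether
# a batch-norm layer follows. This single description drives parameter
# creation, counting, and the forward/backward passes.
conv_table <- function(config) {
  d <- config$depth; bc <- config$base_channels
  lev <- function(l) bc * 2L^(l - 1L)  # channels at encoder level l (1-based)
  rows <- list()
  add <- function(block, j, cin, cout, k) {
    rows[[length(rows) + 1L]] <<- list(block = block, j = j, cin = cin,
                                       cout = cout, k = k,
                                       bn = config$norm == "batch" && block != "out")
  }
  for (l in seq_len(d)) {
    cin <- if (l == 1) config$in_channels else lev(l - 1)
    add(paste0("enc", l), 1L, cin, lev(l), 3L)
    add(paste0("enc", l), 2L, lev(l), lev(l), 3L)
  }
  add("bottleneck", 1L, lev(d), bc * 2L^d, 3L)
  add("bottleneck", 2L, bc * 2L^d, bc * 2L^d, 3L)
  for (l in rev(seq_len(d))) {
    below <- bc * 2L^l
    add(paste0("dec", l), 1L, below + lev(l), lev(l), 3L)
    add(paste0("dec", l), 2L, lev(l), lev(l), 3L)
  }
  add("out", 1L, lev(1), 1L, 1L)
  rows
}

#' Build the segmentation network
#'
#' Creates the full named parameter map. Convolution weights use
#' He-normal initialization (deterministic given `rng_seed`); batch-norm
#' scales start at 1, shifts at 0, running means at 0 and running
#' variances at 1. Batch-norm running statistics are stored in the same
#' map (names ending in `running_mean` / `running_var`) and are treated
#' as client-local state by the federation layer.
#'
#' @param config a [network_config()].
#' @param rng_seed integer seed for the initialization.
#' @return An object of class `fednet`: list with `params` (named list of
#'   arrays) and `config`.
#' @examples
#' net <- build_network(network_config(depth = 1, base_channels = 2), rng_seed = 1)
#' length(net$params)
#' @export
build_network <- function(config, rng_seed) {
  stopifnot(inherits(config, "network_config"))
  tab <- conv_table(config)
  params <- list()
  with_seed(rng_seed, {
    for (r in tab) {
      nm <- sprintf("%s.conv%d", r$block, r$j)
      fan_in <- r$k^3 * r$cin
      params[[paste0(nm, ".weight")]] <-
        array(rnorm(r$k^3 * r$cin * r$cout, sd = sqrt(2 / fan_in)),
              dim = c(r$k, r$k, r$k, r$cin, r$cout))
      params[[paste0(nm, ".bias")]] <- numeric(r$cout)
      if (r$bn) {
        bn <- sprintf("%s.bn%d", r$block, r$j)
        params[[paste0(bn, ".weight")]] <- rep(1, r$cout)
        params[[paste0(bn, ".bias")]] <- numeric(r$cout)
        params[[paste0(bn, ".running_mean")]] <- numeric(r$cout)
        params[[paste0(bn, ".running_var")]] <- rep(1, r$cout)
      }
    }
  })
  structure(list(params = params, config = config), class = "fednet")
}

#' @export
print.fednet <- function(x, ...) {
  cat(sprintf("<fednet: depth %d, base %d channels, %s norm, %d tensors, %d trainable values>\n",
              x$config$depth, x$config$base_channels, x$config$norm,
              length(x$params), n_parameters(x)))
  invisible(x)
}

#' Count network parameter values
#'
#' @param net a `fednet` or a named parameter list.
#' @param include_buffers also count batch-norm running statistics.
#' @return Integer count of scalar values.
#' @export
n_parameters <- function(net, include_buffers = FALSE) {
  params <- if (inherits(net, "fednet")) net$params else net
  nms <- names(params)
  if (!include_buffers) nms <- nms[!grepl("running_(mean|var)$", nms)]
  sum(vapply(params[nms], length, numeric(1)))
}

bn_eps <- 1e-5
bn_momentum <- 0.1

# Per-channel broadcast helper: x is a (vox, C*B) matrix, v has length C.
bc_chan <- function(v, chan, vox) rep(v[chan], each = vox)

bn_forward <- function(x, g, b, rm, rv, train) {
  d <- dim(x); vox <- prod(d[1:3]); C <- d[4]; B <- d[5]
  xm <- x; dim(xm) <- c(vox, C * B)
  chan <- rep(seq_len(C), times = B)
  if (train) {
    percb <- colMeans(xm); dim(percb) <- c(C, B)
    mu <- rowMeans(percb)
    percb2 <- colMeans(xm * xm); dim(percb2) <- c(C, B)
    v <- pmax(rowMeans(percb2) - mu^2, 0)
  } else {
    mu <- rm; v <- rv
  }
  inv <- 1 / sqrt(v + bn_eps)
  xhat <- (xm - bc_chan(mu, chan, vox)) * bc_chan(inv, chan, vox)
  y <- xhat * bc_chan(g, chan, vox) + bc_chan(b, chan, vox)
  dim(y) <- d
  buffers <- NULL
  if (train) {
    buffers <- list(running_mean = (1 - bn_momentum) * rm + bn_momentum * mu,
                    running_var  = (1 - bn_momentum) * rv + bn_momentum * v)
  }
  list(y = y, cache = list(xhat = xhat, inv = inv, g = g, d = d, chan = chan,
                           vox = vox, train = train),
       buffers = buffers)
}

bn_backward <- function(dy, cache) {
  d <- cache$d; vox <- cache$vox; C <- d[4]; B <- d[5]
  chan <- cache$chan
  dym <- dy; dim(dym) <- c(vox, C * B)
  xhat <- cache$xhat
  sum_cb <- function(m) { s <- colSums(m); dim(s) <- c(C, B); rowSums(s) }
  dg <- sum_cb(dym * xhat)
  db <- sum_cb(dym)
  dxhat <- dym * bc_chan(cache$g, chan, vox)
  if (cache$train) {
    n <- vox * B
    s1 <- sum_cb(dxhat)
    s2 <- sum_cb(dxhat * xhat)
    dx <- bc_chan(cache$inv / n, chan, vox) *
      (n * dxhat - bc_chan(s1, chan, vox) - xhat * bc_chan(s2, chan, vox))
  } else {
    dx <- dxhat * bc_chan(cache$inv, chan, vox)
  }
  dim(dx) <- d
  list(dx = dx, dg = dg, db = db)
}

# Run one conv[+bn]+relu twice (a U-Net block); returns output, a tape for
# the backward pass, and any updated batch-norm buffers.
run_block <- function(params, block, h, train, has_bn) {
  tape <- list()
  buffers <- list()
  for (j in 1:2) {
    cw <- sprintf("%s.conv%d.weight", block, j)
    cb <- sprintf("%s.conv%d.bias", block, j)
    x_in <- h
    h <- .conv3d_fwd(h, params[[cw]], params[[cb]])
    rec <- list(wname = cw, bname = cb, x = x_in)
    if (has_bn) {
      bn <- sprintf("%s.bn%d", block, j)
      bf <- bn_forward(h, params[[paste0(bn, ".weight")]], params[[paste0(bn, ".bias")]],
                       params[[paste0(bn, ".running_mean")]], params[[paste0(bn, ".running_var")]],
                       train)
      h <- bf$y
      rec$bn <- bn
      rec$bn_cache <- bf$cache
      if (!is.null(bf$buffers)) {
        buffers[[paste0(bn, ".running_mean")]] <- bf$buffers$running_mean
        buffers[[paste0(bn, ".running_var")]] <- bf$buffers$running_var
      }
    }
    mask <- h > 0
    h <- h * mask
    rec$relu_mask <- mask
    tape[[j]] <- rec
  }
  list(h = h, tape = tape, buffers = buffers)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Coerce a patch to the internal 5-D layout (D1, D2, D3, C, B).
as_batch5d <- function(x, in_channels) {
  d <- dim(x)
  if (length(d) == 3) d <- c(d, 1L, 1L)
  else if (length(d) == 4) d <- c(d, 1L)  # (D,H,W,C) single sample
  else if (length(d) != 5) stopf("input must be a 3-D, 4-D or 5-D array")
  if (d[4] != in_channels) {
    stopf("input has %d channel(s) but the network expects %d", d[4], in_channels)
  }
  dim(x) <- d
  x
}

#' Forward pass of the network
#'
#' Maps a patch (or batch of patches) to voxelwise lesion probabilities
#' of identical spatial shape. In training mode batch statistics are used
#' for normalization and running statistics are updated; in evaluation
#' mode the stored running statistics are used.
#'
#' @param params named parameter list (from [build_network()], possibly
#'   assembled per client).
#' @param config the [network_config()].
#' @param x input array: `(D, H, W)`, `(D, H, W, C)` or `(D, H, W, C, B)`.
#' @param train logical; training mode.
#' @param with_tape keep intermediate activations for a backward pass
#'   (internal use by the training loop).
#' @return List with `prob` (array `(D, H, W, B)` of probabilities),
#'   `buffers` (updated running statistics, training mode only) and, if
#'   requested, the backward tape.
#' @export
fednet_forward <- function(params, config, x, train = FALSE, with_tape = FALSE) {
  x <- as_batch5d(x, config$in_channels)
  d <- dim(x)
  div <- 2L^config$depth
  for (ax in 1:3) {
    if (d[ax] %% div != 0) {
      stopf("input axis %d (size %d) is not divisible by 2^depth = %d", ax, d[ax], div)
    }
  }
  has_bn <- config$norm == "batch"
  buffers <- list()
  skips <- list(); pool_idx <- list(); pre_pool_dim <- list()
  enc_tapes <- list(); dec_tapes <- list()
  h <- x
  for (l in seq_len(config$depth)) {
    rb <- run_block(params, paste0("enc", l), h, train, has_bn)
    buffers[names(rb$buffers)] <- rb$buffers
    skips[[l]] <- rb$h
    enc_tapes[[l]] <- rb$tape
    pr <- .maxpool3d_fwd(rb$h)
    pool_idx[[l]] <- pr$idx
    pre_pool_dim[[l]] <- dim(rb$h)
    h <- pr$y
  }
  rb <- run_block(params, "bottleneck", h, train, has_bn)
  buffers[names(rb$buffers)] <- rb$buffers
  bott_tape <- rb$tape
  h <- rb$h
  skip_channels <- integer(config$depth)
  for (l in rev(seq_len(config$depth))) {
    h <- .upsample3d_fwd(h)
    s <- skips[[l]]
    sc <- dim(s)[4]; hc <- dim(h)[4]
    skip_channels[l] <- sc
    cat_dim <- dim(h); cat_dim[4] <- sc + hc
    hh <- array(0, dim = cat_dim)
    hh[, , , seq_len(sc), ] <- s
    hh[, , , sc + seq_len(hc), ] <- h
    rb <- run_block(params, paste0("dec", l), hh, train, has_bn)
    buffers[names(rb$buffers)] <- rb$buffers
    dec_tapes[[l]] <- rb$tape
    h <- rb$h
  }
  out_x <- h
  logits <- .conv3d_fwd(h, params[["out.conv1.weight"]], params[["out.conv1.bias"]])
  prob <- 1 / (1 + exp(-logits))
  res <- list(prob = array(prob, dim = c(d[1:3], d[5])), buffers = buffers)
  if (with_tape) {
    res$tape <- list(enc = enc_tapes, dec = dec_tapes, bottleneck = bott_tape,
                     pool_idx = pool_idx, pre_pool_dim = pre_pool_dim,
                     skip_channels = skip_channels, out_x = out_x,
                     prob5 = prob, depth = config$depth)
  }
  res
}

# Backward pass: dprob has the shape of `prob`; returns named gradients
# for every trainable parameter (running statistics excluded).
fednet_backward <- function(params, tape, dprob) {
  p <- tape$prob5
  dlogits <- array(dprob, dim = dim(p)) * p * (1 - p)
  cb <- .conv3d_bwd(tape$out_x, params[["out.conv1.weight"]], dlogits)
  gl <- list(out.conv1.weight = cb$dw, out.conv1.bias = cb$db)
  blk_bwd <- function(tp, dy) {
    for (j in 2:1) {
      rec <- tp[[j]]
      dy <- dy * rec$relu_mask
      if (!is.null(rec$bn)) {
        bb <- bn_backward(dy, rec$bn_cache)
        gl[[paste0(rec$bn, ".weight")]] <<- (gl[[paste0(rec$bn, ".weight")]] %||% 0) + bb$dg
        gl[[paste0(rec$bn, ".bias")]] <<- (gl[[paste0(rec$bn, ".bias")]] %||% 0) + bb$db
        dy <- bb$dx
      }
      cbk <- .conv3d_bwd(rec$x, params[[rec$wname]], dy)
      gl[[rec$wname]] <<- (gl[[rec$wname]] %||% 0) + cbk$dw
      gl[[rec$bname]] <<- (gl[[rec$bname]] %||% 0) + cbk$db
      dy <- cbk$dx
    }
    dy
  }
  dh <- cb$dx
  dskips <- vector("list", tape$depth)
  for (l in seq_len(tape$depth)) {
    dh <- blk_bwd(tape$dec[[l]], dh)
    sc <- tape$skip_channels[l]
    hc <- dim(dh)[4] - sc
    dskips[[l]] <- dh[, , , seq_len(sc), , drop = FALSE]
    dbelow <- dh[, , , sc + seq_len(hc), , drop = FALSE]
    dim(dskips[[l]]) <- c(dim(dh)[1:3], sc, dim(dh)[5])
    dim(dbelow) <- c(dim(dh)[1:3], hc, dim(dh)[5])
    dh <- .upsample3d_bwd(dbelow)
  }
  dh <- blk_bwd(tape$bottleneck, dh)
  for (l in rev(seq_len(tape$depth))) {
    dh <- .maxpool3d_bwd(dh, tape$pool_idx[[l]], as.integer(tape$pre_pool_dim[[l]]))
    dh <- dh + dskips[[l]]
    dh <- blk_bwd(tape$enc[[l]], dh)
  }
  gl
}

#' Partition parameter names into normalization-local and shared sets
#'
#' Splits a network's named parameter map into the batch-norm set (affine
#' weights, biases, and running statistics -- the client-local state under
#' FedBN-style training) and the complementary shared set. The two sets
#' form a true bipartition of all names.
#'
#' @param params a `fednet`, or a named parameter list from one.
#' @return Object of class `parameter_partition`: list with `bn_names`
#'   and `rest_names` in the map's order.
#' @export
partition_parameters <- function(params) {
  if (inherits(params, "fednet")) params <- params$params
  nms <- names(params)
  if (is.null(nms) || any(!nzchar(nms))) stopf("parameters must be a named list")
  is_bn <- grepl("\\.bn[0-9]+\\.(weight|bias|running_mean|running_var)$", nms)
  is_conv <- grepl("\\.conv[0-9]+\\.(weight|bias)$", nms)
  unknown <- nms[!is_bn & !is_conv]
  if (length(unknown)) {
    stopf("unknown parameter name(s): %s", paste(unknown, collapse = ", "))
  }
  structure(list(bn_names = nms[is_bn], rest_names = nms[is_conv]),
            class = "parameter_partition")
}

#' @export
print.parameter_partition <- function(x, ...) {
  cat(sprintf("<parameter_partition: %d normalization-local, %d shared names>\n",
              length(x$bn_names), length(x$rest_names)))
  invisible(x)
}

#' Assemble a client model from shared and client-local parameters
#'
#' Combines the globally aggregated shared parameters with one client's
#' private normalization parameters (including running statistics) into a
#' full parameter map, in the canonical order given by `partition`.
#'
#' @param global_rest named list of values over the shared names.
#' @param client_bn named list of values over the normalization names.
#' @param partition optional [partition_parameters()] result used to
#'   verify that the two inputs exactly tile the network's names.
#' @return Full named parameter list.
#' @export
assemble_client_parameters <- function(global_rest, client_bn, partition = NULL) {
  both <- c(names(global_rest), names(client_bn))
  if (anyDuplicated(both)) {
    stopf("overlapping names: %s", paste(both[duplicated(both)], collapse = ", "))
  }
  if (!is.null(partition)) {
    want <- c(partition$rest_names, partition$bn_names)
    missing <- setdiff(want, both)
    extra <- setdiff(both, want)
    if (length(missing) || length(extra)) {
      stopf("parameter names do not tile the network: missing [%s], extra [%s]",
            paste(missing, collapse = ", "), paste(extra, collapse = ", "))
    }
    # reconstruct the build order: each conv's bn tensors follow its bias
    order_names <- character(0)
    for (nm in partition$rest_names) {
      order_names <- c(order_names, nm)
      if (grepl("\\.conv[0-9]+\\.bias$", nm)) {
        bnprefix <- sub("conv([0-9]+)\\.bias$", "bn\\1.", nm)
        order_names <- c(order_names,
                         partition$bn_names[startsWith(partition$bn_names, bnprefix)])
      }
    }
    order_names <- c(order_names, setdiff(partition$bn_names, order_names))
  } else {
    order_names <- both
  }
  full <- c(global_rest, client_bn)
  full[order_names]
}

#' Save / load a checkpoint
#'
#' Checkpoints are flat named-value containers (plus the partition name
#' lists) with a bit-exact save/load round trip.
#'
#' @param params named parameter list.
#' @param path file path.
#' @param partition optional `parameter_partition` stored alongside.
#' @return `load_checkpoint` returns a list with `params` and `partition`.
#' @export
save_checkpoint <- function(params, path, partition = NULL) {
  saveRDS(list(params = params, partition = partition), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)
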