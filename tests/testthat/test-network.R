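test_that("forward pass preserves shape and stays within [0, 1]", {
  nc <- tiny_net_config(depth = 1, base = 2)
  net <- build_network(nc, rng_seed = 1)
  x <- array(rnorm(8^3), dim = c(8, 8, 8))
  fw <- fednet_forward(net$params, nc, x)
  expect_identical(dim(fw$prob), c(8L, 8L, 8L, 1L))
  expect_true(all(fw$prob >= 0 & fw$prob <= 1))
})

test_that("initialization is deterministic in the seed", {
  nc <- tiny_net_config(depth = 2, base = 2)
  expect_identical(build_network(nc, 42)$params, build_network(nc, 42)$params)
  expect_false(identical(build_network(nc, 42)$params, build_network(nc, 43)$params))
})

test_that("parameter count matches an independent layer-by-layer count", {
  nc <- network_config(in_channels = 1, depth = 2, base_channels = 4)
  net <- build_network(nc, 1)
  # walk the architecture by hand: conv weights k^3*cin*cout + cout biases,
  # plus 2 affine values per channel for each batch-norm layer
  conv <- function(cin, cout, k = 3) k^3 * cin * cout + cout
  bn <- function(c) 2 * c
  expected <-
    conv(1, 4) + bn(4) + conv(4, 4) + bn(4) +          # enc1
    conv(4, 8) + bn(8) + conv(8, 8) + bn(8) +          # enc2
    conv(8, 16) + bn(16) + conv(16, 16) + bn(16) +     # bottleneck
    conv(24, 8) + bn(8) + conv(8, 8) + bn(8) +         # dec2 (16 up + 8 skip)
    conv(12, 4) + bn(4) + conv(4, 4) + bn(4) +         # dec1 (8 up + 4 skip)
    conv(4, 1, k = 1)                                  # output head
  expect_identical(n_parameters(net), expected)
})

test_that("partition is a true bipartition covering all names", {
  nc <- tiny_net_config(depth = 2, base = 2)
  net <- build_network(nc, 1)
  part <- partition_parameters(net)
  expect_length(intersect(part$bn_names, part$rest_names), 0)
  expect_setequal(c(part$bn_names, part$rest_names), names(net$params))
  # every bn layer contributes weight, bias and both running statistics:
  # depth-2 U-Net has 2 norm layers in each of 5 blocks
  expect_length(part$bn_names, 4 * 10)
  expect_true(all(grepl("\\.bn[0-9]+\\.", part$bn_names)))
  expect_error(partition_parameters(list(foo = 1)), "unknown parameter")
})

test_that("a norm-free network has an empty normalization set", {
  nc <- network_config(depth = 1, base_channels = 2, norm = "none")
  net <- build_network(nc, 1)
  part <- partition_parameters(net)
  expect_length(part$bn_names, 0)
  expect_setequal(part$rest_names, names(net$params))
  fw <- fednet_forward(net$params, nc, array(rnorm(8^3), c(8, 8, 8)))
  expect_true(all(is.finite(fw$prob)))
})

test_that("assemble o partition is the identity and edits are local", {
  nc <- tiny_net_config(depth = 2, base = 2)
  net <- build_network(nc, 1)
  part <- partition_parameters(net)
  rest <- net$params[part$rest_names]
  bn <- net$params[part$bn_names]
  expect_identical(assemble_client_parameters(rest, bn, part), net$params)
  bn2 <- bn
  bn2[[1]][1] <- 99
  asm <- assemble_client_parameters(rest, bn2, part)
  changed <- !mapply(identical, asm, net$params)
  expect_identical(names(which(changed)), part$bn_names[1])
  # two clients sharing global rest differ only on bn names
  asm2 <- assemble_client_parameters(rest, bn, part)
  diffs <- names(which(!mapply(identical, asm, asm2)))
  expect_true(all(diffs %in% part$bn_names))
  expect_error(assemble_client_parameters(rest[-1], bn, part), "missing")
  expect_error(assemble_client_parameters(c(rest, list(zzz = 1)), bn, part), "extra")
})

test_that("forward rejects patches not divisible by 2^depth, naming the axis", {
  nc <- tiny_net_config(depth = 2, base = 2)
  net <- build_network(nc, 1)
  expect_error(fednet_forward(net$params, nc, array(0, c(8, 6, 8))),
               "axis 2 \\(size 6\\)")
})

test_that("analytic gradients agree with finite differences", {
  nc <- tiny_net_config(depth = 1, base = 2)
  net <- build_network(nc, 1)
  set.seed(3)
  x <- array(rnorm(8^3 * 2), dim = c(8, 8, 8, 1, 2))
  y <- array(as.numeric(runif(8^3 * 2) < 0.2), dim = c(8, 8, 8, 2))
  loss_of <- function(params) {
    fw <- fednet_forward(params, nc, x, train = TRUE)
    soft_dice_loss(fw$prob, y)
  }
  fw <- fednet_forward(net$params, nc, x, train = TRUE, with_tape = TRUE)
  dprob <- fedlesion:::soft_dice_grad(fw$prob, y)
  grads <- fedlesion:::fednet_backward(net$params, fw$tape, dprob)
  for (nm in c("enc1.conv1.weight", "enc1.bn2.weight", "enc1.bn1.bias",
               "bottleneck.conv2.weight", "dec1.conv1.weight", "out.conv1.bias")) {
    set.seed(nchar(nm))
    i <- sample(length(net$params[[nm]]), 1)
    eps <- 1e-5
    up <- net$params; up[[nm]][i] <- up[[nm]][i] + eps
    dn <- net$params; dn[[nm]][i] <- dn[[nm]][i] - eps
    numeric_grad <- (loss_of(up) - loss_of(dn)) / (2 * eps)
    expect_equal(grads[[nm]][i], numeric_grad, tolerance = 1e-5,
                 label = sprintf("gradient of %s", nm))
  }
})

test_that("training-mode forward updates running statistics; eval mode does not", {
  nc <- tiny_net_config(depth = 1, base = 2)
  net <- build_network(nc, 1)
  x <- array(rnorm(8^3) * 10 + 3, dim = c(8, 8, 8))
  fw_train <- fednet_forward(net$params, nc, x, train = TRUE)
  expect_gt(length(fw_train$buffers), 0)
  expect_false(identical(fw_train$buffers[["enc1.bn1.running_mean"]],
                         net$params[["enc1.bn1.running_mean"]]))
  fw_eval <- fednet_forward(net$params, nc, x, train = FALSE)
  expect_length(fw_eval$buffers, 0)
})

test_that("checkpoints round-trip bit-exactly", {
  nc <- tiny_net_config(depth = 1, base = 2)
  net <- build_network(nc, 8)
  part <- partition_parameters(net)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(net$params, path, part)
  back <- load_checkpoint(path)
  expect_identical(back$params, net$params)
  expect_identical(back$partition, part)
})
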