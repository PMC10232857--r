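# Shared fixtures: everything is generated in code at test time.

tiny_profiles <- function(shape = 16, n_cases = 4,
                          ratios = c(0.02, 0.04),
                          offsets = c(0, 40)) {
  list(
    client_profile("siteA", n_cases, volume_shape = shape,
                   target_ratio = ratios[1], lesion_radius_range = c(1.5, 2.5),
                   intensity_offset = offsets[1], noise_sigma = 2),
    client_profile("siteB", n_cases, volume_shape = shape,
                   target_ratio = ratios[2], lesion_radius_range = c(1.5, 2.5),
                   intensity_offset = offsets[2], noise_sigma = 2))
}

tiny_net_config <- function(depth = 1, base = 2) {
  network_config(in_channels = 1, depth = depth, base_channels = base)
}

tiny_fed_config <- function(mode, rounds = 2, iters = 2, seed = 1,
                            patch = 8, batch = 2, lr = 0.02, ...) {
  federation_config(mode = mode, n_rounds = rounds, iters_per_round = iters,
                    lr = lr, batch_size = batch,
                    patch_size = rep(patch, 3), master_seed = seed, ...)
}

# A model whose output probability is constant everywhere: the final
# 1x1x1 convolution ignores its input.
constant_model <- function(net_config, logit = 0.7, seed = 1) {
  net <- build_network(net_config, seed)
  net$params[["out.conv1.weight"]][] <- 0
  net$params[["out.conv1.bias"]][] <- logit
  net
}

random_binary_array <- function(shape, p = 0.3) {
  array(as.integer(runif(prod(shape)) < p), dim = shape)
}
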