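test_that("loss re-weighting factor matches direct evaluation", {
  # equal ratios: every client gets weight 1
  expect_equal(loss_weight(c(0.02, 0.02, 0.02), 2), 1, tolerance = 1e-12)
  # hand-computed two-client case
  expect_equal(loss_weight(c(0.01, 0.03), 1), 2, tolerance = 1e-12)
  expect_equal(loss_weight(c(0.01, 0.03), 2), 2 / 3, tolerance = 1e-12)
  # conservation when no clipping triggers: sum(w * vr) == sum(vr)
  set.seed(5)
  for (rep in 1:50) {
    n <- sample(2:6, 1)
    vr <- runif(n, 0.01, 0.05)  # bounded so weights stay inside [0.1, 10]
    w <- vapply(seq_len(n), function(i) loss_weight(vr, i), numeric(1))
    expect_equal(sum(w * vr), sum(vr), tolerance = 1e-9)
  }
  # clipping guards degenerate ratios
  expect_equal(loss_weight(c(0, 0.05), 1), 10)
  expect_lt(loss_weight(c(1, 1e-9), 1), 0.5 + 1e-6)
  expect_error(loss_weight(numeric(0), 1), "empty")
})

test_that("uniform aggregation is the per-entry mean; selection is respected", {
  a <- list(w = array(0, c(2, 2)), b = 1, bn = 5)
  b <- list(w = array(1, c(2, 2)), b = 3, bn = 9)
  got <- average_aggregate(list(a, b), c("w", "b"))
  expect_equal(got$w, array(0.5, c(2, 2)))
  expect_equal(got$b, 2)
  expect_null(got$bn)            # non-selected entries stay client-local
  expect_identical(names(got), c("w", "b"))
  one <- average_aggregate(list(a), names(a))
  expect_equal(one, a[names(a)])
  expect_error(average_aggregate(list(a, list(w = array(1, c(3, 2)), b = 1)), "w"),
               "shape mismatch")
})

test_that("ability-weighted aggregation matches a brute-force weighted mean", {
  # hand case: entries 0 and 1, abilities 1 and 3 -> 0.75
  a <- list(x = 0); b <- list(x = 1)
  expect_equal(weighted_aggregate(list(a, b), c(1, 3), "x")$x, 0.75, tolerance = 1e-12)
  # zero ability removes influence entirely
  expect_equal(weighted_aggregate(list(a, b), c(1, 0), "x")$x, 0)
  # equal abilities reduce bitwise to the uniform mean
  set.seed(8)
  maps <- lapply(1:3, function(k) list(u = array(rnorm(10), 10), v = rnorm(1)))
  expect_identical(weighted_aggregate(maps, c(0.4, 0.4, 0.4), c("u", "v")),
                   average_aggregate(maps, c("u", "v")))
  # brute force per entry on random 10-entry maps
  for (rep in 1:20) {
    n <- sample(2:5, 1)
    maps <- lapply(seq_len(n), function(k) {
      stats::setNames(lapply(1:10, function(j) rnorm(3)), paste0("p", 1:10))
    })
    ab <- runif(n, 0.1, 1)
    got <- weighted_aggregate(maps, ab, paste0("p", 1:10))
    for (nm in paste0("p", 1:10)) {
      brute <- Reduce(`+`, Map(function(m, w) m[[nm]] * w, maps, ab / sum(ab)))
      expect_equal(got[[nm]], brute, tolerance = 1e-6)
    }
  }
  expect_error(weighted_aggregate(list(a, b), c(0, 0), "x"), "all abilities")
})

test_that("increasing one client's ability moves the aggregate toward it", {
  a <- list(x = 0); b <- list(x = 1)
  vals <- vapply(seq(0.5, 5, by = 0.5), function(p2) {
    weighted_aggregate(list(a, b), c(1, p2), "x")$x
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_true(all(vals > 0 & vals < 1))
})

test_that("a zero learning rate leaves trainable parameters unchanged", {
  fed <- generate_federation(tiny_profiles(), 3)
  nc <- tiny_net_config()
  net <- build_network(nc, 1)
  cfg <- tiny_fed_config("fedavg", iters = 1, lr = 0)
  res <- local_train_round(fed$siteA, net$params, cfg, nc, rng_seed = 2)
  trainable <- setdiff(names(net$params),
                       grep("running_(mean|var)$", names(net$params), value = TRUE))
  expect_identical(res$params[trainable], net$params[trainable])
  expect_true(is.finite(res$round_mean_ratio))
  expect_true(res$round_mean_ratio >= 0)
  expect_true(is.finite(res$mean_loss))
})

test_that("scaling the loss weight is equivalent to scaling the learning rate", {
  fed <- generate_federation(tiny_profiles(), 3)
  nc <- tiny_net_config()
  net <- build_network(nc, 1)
  cfg1 <- tiny_fed_config("fedavg", iters = 1, lr = 0.02)
  cfg1$momentum <- 0; cfg1$weight_decay <- 0
  cfg2 <- cfg1; cfg2$lr <- 0.01
  r1 <- local_train_round(fed$siteA, net$params, cfg1, nc,
                          global_loss_weight = 1, rng_seed = 9)
  r2 <- local_train_round(fed$siteA, net$params, cfg2, nc,
                          global_loss_weight = 2, rng_seed = 9)
  for (nm in names(net$params)) {
    expect_equal(r1$params[[nm]], r2$params[[nm]], tolerance = 1e-12,
                 label = nm)
  }
})

test_that("degenerate settings reduce strategies to their baselines bitwise", {
  fed <- generate_federation(tiny_profiles(), 5)
  nc <- tiny_net_config()
  # fedprox with mu = 0 is fedavg
  prox0 <- run_federation(fed, tiny_fed_config("fedprox", prox_mu = 0), nc)
  avg <- run_federation(fed, tiny_fed_config("fedavg"), nc)
  expect_identical(prox0$client_params, avg$client_params)
  # fedprox with mu > 0 differs
  prox <- run_federation(fed, tiny_fed_config("fedprox", prox_mu = 10), nc)
  expect_false(identical(prox$client_params, avg$client_params))
})

test_that("after aggregation all clients share identical shared parameters", {
  fed <- generate_federation(tiny_profiles(), 6)
  nc <- tiny_net_config()
  fit <- run_federation(fed, tiny_fed_config("fedmsrw", rounds = 2), nc)
  part <- fit$partition
  p1 <- fit$client_params[[1]][part$rest_names]
  p2 <- fit$client_params[[2]][part$rest_names]
  expect_identical(p1, p2)
  # bn state is private and has genuinely diverged across clients
  expect_false(identical(fit$client_params[[1]][part$bn_names],
                         fit$client_params[[2]][part$bn_names]))
})

test_that("aggregation weights from the history always sum to one", {
  fed <- generate_federation(tiny_profiles(), 6)
  nc <- tiny_net_config()
  for (mode in c("fedavg", "fedbn", "fedmsrw", "ours_ent", "ours_vol")) {
    fit <- run_federation(fed, tiny_fed_config(mode, rounds = 2), nc)
    sums <- tapply(fit$history$agg_weight, fit$history$round, sum)
    expect_true(all(abs(sums - 1) < 1e-9), label = mode)
  }
})

test_that("single-step federation matches a hand-computed weighted mean", {
  # P=1, Q=1, two clients: final shared parameters must equal the
  # ability-weighted mean of the two locally trained parameter maps
  fed <- generate_federation(tiny_profiles(), 9)
  nc <- tiny_net_config()
  cfg <- tiny_fed_config("fedmsrw", rounds = 1, iters = 1, seed = 4)
  fit <- run_federation(fed, cfg, nc)
  # replay the two local rounds with the same derived seeds
  net <- build_network(nc, fedlesion:::derive_seed(cfg$master_seed, 1))
  part <- partition_parameters(net)
  locals <- list(); abilities <- numeric(2)
  ids <- sort(names(fed))
  for (ci in seq_along(ids)) {
    r <- local_train_round(fed[[ids[ci]]], net$params, cfg, nc,
                           rng_seed = fedlesion:::derive_seed(cfg$master_seed, 1, ci))
    locals[[ci]] <- r$params
    abilities[ci] <- r$round_ability
  }
  pres <- !is.na(abilities)
  abilities[!pres] <- mean(abilities[pres])
  w <- abilities / sum(abilities)
  for (nm in part$rest_names) {
    brute <- locals[[1]][[nm]] * w[1] + locals[[2]][[nm]] * w[2]
    expect_equal(fit$global_rest[[nm]], brute, tolerance = 1e-12, label = nm)
  }
})

test_that("round-one training uses unit loss weights and later rounds re-weight", {
  # high, clearly separated lesion burdens and whole-volume patches so both
  # clients observe lesions in round 1 and no loss-weight clipping triggers
  profiles <- list(
    client_profile("lowB", 4, volume_shape = 16, lesion_count_mean = 2,
                   lesion_radius_range = c(1.5, 2.5), noise_sigma = 2),
    client_profile("highB", 4, volume_shape = 16, lesion_count_mean = 6,
                   lesion_radius_range = c(1.5, 2.5), noise_sigma = 2))
  fed <- generate_federation(profiles, 10)
  nc <- tiny_net_config()
  fit <- run_federation(fed, tiny_fed_config("fedmsrw", rounds = 2, patch = 16), nc)
  h <- fit$history
  # weights recorded at round p apply to round p+1; the low-burden client
  # gets the larger weight
  r1 <- h[h$round == 1, ]
  expect_gt(r1$next_loss_weight[r1$client == "lowB"],
            r1$next_loss_weight[r1$client == "highB"])
  unclipped <- all(r1$next_loss_weight > 0.1 & r1$next_loss_weight < 10)
  expect_true(unclipped)
  expect_equal(sum(r1$next_loss_weight * r1$vr), sum(r1$vr), tolerance = 1e-9)
})

test_that("ablation modes isolate exactly one re-weighting component", {
  fed <- generate_federation(tiny_profiles(), 31)
  nc <- tiny_net_config()
  # aggregation-only ablation == full method with unit loss weights
  ca <- run_federation(fed, tiny_fed_config("fedmsrw_ca_only", rounds = 2), nc)
  msrw_unit <- run_federation(fed, tiny_fed_config("fedmsrw", rounds = 2,
                                                   loss_weight_override = 1), nc)
  expect_identical(ca$client_params, msrw_unit$client_params)
  # loss-only ablation with unit weights == plain FedBN
  lt_unit <- run_federation(fed, tiny_fed_config("fedmsrw_lt_only", rounds = 2,
                                                 loss_weight_override = 1), nc)
  fb <- run_federation(fed, tiny_fed_config("fedbn", rounds = 2), nc)
  expect_identical(lt_unit$client_params, fb$client_params)
  # the voxel-count variant tracks counts, not ratios, in its weights
  ov <- run_federation(fed, tiny_fed_config("ours_vol", rounds = 2), nc)
  h <- ov$history[ov$history$round == 1, ]
  expect_equal(h$next_loss_weight,
               vapply(seq_len(nrow(h)), function(i) loss_weight(h$v_voxels, i),
                      numeric(1)), tolerance = 1e-12)
})
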