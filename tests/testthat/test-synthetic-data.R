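test_that("generated cases satisfy the mask and background invariants", {
  profiles <- tiny_profiles()
  fed <- generate_federation(profiles, rng_seed = 11)
  for (cases in fed) for (case in cases) {
    expect_equal(sum(case$lesion_mask & !case$brain_mask), 0)
    expect_true(all(case$volume[case$brain_mask == 0] == 0))
    expect_identical(dim(case$volume), dim(case$lesion_mask))
  }
})

test_that("the generator is a pure function of profile and seed", {
  p <- tiny_profiles()[[1]]
  a <- generate_case(p, rng_seed = 5)
  b <- generate_case(p, rng_seed = 5)
  expect_identical(a, b)
  c2 <- generate_case(p, rng_seed = 6)
  expect_false(identical(a$volume, c2$volume))
  # caller's RNG stream is untouched
  set.seed(99); before <- runif(3)
  set.seed(99); invisible(generate_case(p, rng_seed = 5)); after <- runif(3)
  expect_identical(before, after)
})

test_that("a forced single lesion of fixed radius yields one compact sphere", {
  p <- client_profile("deg", 1, volume_shape = 24, noise_sigma = 0,
                      lesion_count_mean = 1, lesion_radius_range = c(3, 3))
  case <- generate_case(p, rng_seed = 3, n_lesions = 1)
  vox <- which(case$lesion_mask == 1, arr.ind = TRUE)
  expect_gt(nrow(vox), 0)
  # bounding box of a radius-3 sphere spans at most 7 voxels per axis
  expect_true(all(apply(vox, 2, function(v) diff(range(v))) <= 6))
  # voxel count of a Euclidean ball of radius 3 (center may be off-grid)
  expect_gt(nrow(vox), 60)
  expect_lt(nrow(vox), 200)
})

test_that("empirical lesion-to-brain ratio converges to target_ratio", {
  p <- client_profile("mc", 1, volume_shape = 32, target_ratio = 0.01,
                      lesion_radius_range = c(2, 3), noise_sigma = 0)
  ratios <- vapply(1:100, function(s) {
    case <- generate_case(p, rng_seed = s)
    sum(case$lesion_mask) / sum(case$brain_mask)
  }, numeric(1))
  expect_gt(mean(ratios), 0.01 * 0.7)
  expect_lt(mean(ratios), 0.01 * 1.3)
})

test_that("per-client intensity offsets separate client brain intensities", {
  profiles <- list(
    client_profile("lo", 4, volume_shape = 16, intensity_offset = 0,
                   noise_sigma = 0, target_ratio = 0.02,
                   lesion_radius_range = c(1.5, 2.5)),
    client_profile("hi", 4, volume_shape = 16, intensity_offset = 50,
                   noise_sigma = 0, target_ratio = 0.02,
                   lesion_radius_range = c(1.5, 2.5)))
  fed <- generate_federation(profiles, rng_seed = 2)
  mean_brain <- function(cases) {
    mean(vapply(cases, function(c) mean(c$volume[c$brain_mask == 1]), numeric(1)))
  }
  expect_equal(mean_brain(fed$hi) - mean_brain(fed$lo), 50, tolerance = 0.05)
})

test_that("per-client seed streams are isolated", {
  profiles <- tiny_profiles()
  fed1 <- generate_federation(profiles, rng_seed = 7)
  # change the second client's profile; the first client must be unaffected
  profiles2 <- profiles
  profiles2[[2]] <- client_profile("siteB", 4, volume_shape = 16,
                                   target_ratio = 0.03,
                                   lesion_radius_range = c(1.5, 2.5),
                                   intensity_offset = 99, noise_sigma = 7)
  fed2 <- generate_federation(profiles2, rng_seed = 7)
  expect_identical(fed1$siteA, fed2$siteA)
  expect_equal(lengths(fed1), c(siteA = 4L, siteB = 4L))
  expect_error(generate_federation(profiles[c(1, 1)], 1), "duplicate")
  expect_error(generate_federation(profiles[1], 1), "at least 2")
})

test_that("patch sampling stays inside the volume and respects offsets", {
  shape <- c(48L, 48L, 48L)
  vol <- array(seq_len(prod(shape)), dim = shape)
  case <- list(volume = vol, lesion_mask = array(0L, shape))
  for (s in 1:20) {
    pt <- sample_patch(case, c(32, 32, 32), rng_seed = s)
    # recover the offset from the linear-index volume
    first <- pt$volume[1, 1, 1]
    off <- c((first - 1) %% 48, ((first - 1) %/% 48) %% 48, (first - 1) %/% 48^2)
    expect_true(all(off >= 0 & off <= 16))
    expect_identical(dim(pt$volume), c(32L, 32L, 32L))
  }
  full <- sample_patch(case, shape, rng_seed = 1)
  expect_identical(full$volume, vol)
  expect_error(sample_patch(case, c(64, 48, 48), rng_seed = 1), "exceeds")
})

test_that("augmentation preserves voxel multisets of patch and mask", {
  p <- tiny_profiles()[[2]]
  case <- generate_case(p, rng_seed = 4)
  for (s in 1:10) {
    plain <- sample_patch(case, c(8, 8, 8), augment = FALSE, rng_seed = s)
    aug <- sample_patch(case, c(8, 8, 8), augment = TRUE, rng_seed = s)
    expect_identical(sort(as.numeric(aug$volume)), sort(as.numeric(plain$volume)))
    expect_identical(sum(aug$mask), sum(plain$mask))
  }
})

test_that("profile construction rejects impossible settings", {
  expect_error(client_profile("x", 2, volume_shape = 8,
                              lesion_radius_range = c(2, 5)), "2 \\* max lesion radius")
  expect_error(client_profile("x", 2, target_ratio = 0.5), "target_ratio")
  expect_error(client_profile("x", 2, intensity_scale = 0), "intensity_scale")
  expect_error(client_profile("", 2), "client_id")
})

test_that("NIfTI round trip preserves volumes and masks", {
  skip_if_not_installed("RNifti")
  fed <- generate_federation(tiny_profiles(n_cases = 2), rng_seed = 3)
  dir <- withr::local_tempdir()
  write_federation_nifti(fed, dir)
  back <- read_federation_nifti(dir)
  expect_setequal(names(back), names(fed))
  for (cid in names(fed)) for (j in seq_along(fed[[cid]])) {
    orig <- fed[[cid]][[j]]
    got <- back[[cid]][[which(vapply(back[[cid]], `[[`, character(1), "case_id") == orig$case_id)]]
    expect_equal(got$volume, orig$volume, tolerance = 1e-6)
    expect_equal(as.integer(got$lesion_mask), as.integer(orig$lesion_mask))
  }
})
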