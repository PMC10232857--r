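#' Describe one client's phantom data distribution
#'
#' A client profile collects the generative parameters for one site in a
#' simulated federation: how many cases it holds, the geometry of the
#' brain phantom, the site-specific intensity transform (modelling
#' scanner/protocol differences), the noise level, and the lesion burden.
#'
#' The per-client intensity transform is `scale * tissue + offset` plus
#' additive Gaussian noise inside the brain; background voxels are exactly
#' zero, emulating brain-extracted input. Lesion burden can be given
#' either directly as `lesion_count_mean` (expected lesions per case) or
#' via `target_ratio`, the intended mean lesion-to-brain volume ratio,
#' from which the expected lesion count is derived using the expected
#' sphere volume for the given radius range.
#'
#' @param client_id character scalar, unique within a federation.
#' @param n_cases number of cases this client holds.
#' @param volume_shape integer triple (voxels per axis); a scalar is
#'   recycled. Each axis must be at least twice the maximum lesion radius.
#' @param brain_radius_frac semi-axes of the brain ellipsoid as a fraction
#'   of each half-extent, in (0, 1].
#' @param intensity_offset additive brightness shift (arbitrary units).
#' @param intensity_scale multiplicative contrast factor, > 0.
#' @param noise_sigma standard deviation of additive Gaussian noise, >= 0.
#' @param lesion_count_mean expected number of lesions per case (Poisson
#'   mean), > 0. Ignored when `target_ratio` is supplied.
#' @param lesion_radius_range numeric pair (min, max) lesion radius in
#'   voxels, min >= 1.
#' @param target_ratio optional intended mean lesion-to-brain volume
#'   ratio, in (0, 0.1). When given, `lesion_count_mean` is derived so the
#'   expected total lesion volume matches `target_ratio` times the brain
#'   volume.
#' @return An object of class `client_profile`.
#' @examples
#' p <- client_profile("siteA", n_cases = 4, volume_shape = 24,
#'                     target_ratio = 0.02)
#' p$lesion_count_mean
#' @export
client_profile <- function(client_id,
                           n_cases,
                           volume_shape = c(64L, 64L, 64L),
                           brain_radius_frac = 0.9,
                           intensity_offset = 0,
                           intensity_scale = 1,
                           noise_sigma = 5,
                           lesion_count_mean = 5,
                           lesion_radius_range = c(2, 4),
                           target_ratio = NULL) {
  if (!is.character(client_id) || length(client_id) != 1 || !nzchar(client_id)) {
    stopf("'client_id' must be a non-empty string")
  }
  if (!is_count(n_cases)) stopf("'n_cases' must be a positive integer")
  volume_shape <- check_triple(volume_shape, "volume_shape")
  if (!is.numeric(brain_radius_frac) || brain_radius_frac <= 0 || brain_radius_frac > 1) {
    stopf("'brain_radius_frac' must lie in (0, 1]")
  }
  if (intensity_scale <= 0) stopf("'intensity_scale' must be > 0")
  if (noise_sigma < 0) stopf("'noise_sigma' must be >= 0")
  if (length(lesion_radius_range) != 2 || lesion_radius_range[1] < 1 ||
      diff(lesion_radius_range) < 0) {
    stopf("'lesion_radius_range' must be (min, max) with min >= 1")
  }
  rmax <- lesion_radius_range[2]
  if (any(volume_shape < 2 * rmax)) {
    stopf("every axis of 'volume_shape' must be >= 2 * max lesion radius (%g)", 2 * rmax)
  }
  semi <- brain_radius_frac * (volume_shape - 1) / 2
  brain_vol <- 4 / 3 * pi * prod(semi)
  # E[4/3 pi R^3] for R ~ U(rmin, rmax)
  rmin <- lesion_radius_range[1]
  er3 <- if (rmax > rmin) (rmax^4 - rmin^4) / (4 * (rmax - rmin)) else rmin^3
  exp_lesion_vol <- 4 / 3 * pi * er3
  if (!is.null(target_ratio)) {
    if (target_ratio <= 0 || target_ratio >= 0.1) {
      stopf("'target_ratio' must lie in (0, 0.1)")
    }
    lesion_count_mean <- target_ratio * brain_vol / exp_lesion_vol
    if (lesion_count_mean < 0.05) {
      stopf("client '%s': target_ratio %.4g is not achievable for this volume shape %s",
            client_id, target_ratio, paste(volume_shape, collapse = "x"))
    }
  }
  if (lesion_count_mean <= 0) stopf("'lesion_count_mean' must be > 0")
  if (min(semi) <= rmax) {
    stopf("client '%s': largest lesion (radius %g) cannot fit inside the brain ellipsoid",
          client_id, rmax)
  }
  structure(list(
    client_id = client_id,
    n_cases = as.integer(n_cases),
    volume_shape = volume_shape,
    brain_radius_frac = brain_radius_frac,
    intensity_offset = intensity_offset,
    intensity_scale = intensity_scale,
    noise_sigma = noise_sigma,
    lesion_count_mean = lesion_count_mean,
    lesion_radius_range = as.numeric(lesion_radius_range),
    target_ratio = if (is.null(target_ratio)) NA_real_ else target_ratio
  ), class = "client_profile")
}

#' @export
print.client_profile <- function(x, ...) {
  cat(sprintf("<client_profile '%s': %d cases, %s voxels, offset %+g, scale %g, noise %g, E[lesions] %.2f>\n",
              x$client_id, x$n_cases, paste(x$volume_shape, collapse = "x"),
              x$intensity_offset, x$intensity_scale, x$noise_sigma, x$lesion_count_mean))
  invisible(x)
}

# Smooth low-frequency tissue field: constant plus a few random 3-D cosines,
# so the phantom has learnable texture without sharp structure.
tissue_field <- function(shape, n_waves = 4, base = 100, amp_range = c(5, 15)) {
  g1 <- seq_len(shape[1]); g2 <- seq_len(shape[2]); g3 <- seq_len(shape[3])
  field <- array(base, dim = shape)
  for (k in seq_len(n_waves)) {
    f <- runif(3, 0.02, 0.08)
    ph <- runif(3, 0, 2 * pi)
    amp <- runif(1, amp_range[1], amp_range[2])
    w1 <- cos(2 * pi * f[1] * g1 + ph[1])
    w2 <- cos(2 * pi * f[2] * g2 + ph[2])
    w3 <- cos(2 * pi * f[3] * g3 + ph[3])
    field <- field + amp * (outer(outer(w1, w2), w3))
  }
  field
}

#' Generate one synthetic brain-phantom case
#'
#' Builds an ellipsoidal "brain" filled with a smooth tissue intensity
#' field, places a Poisson-distributed number of hyperintense spherical
#' lesions fully inside the brain, applies the client's intensity
#' transform, and adds Gaussian noise inside the brain. Background is
#' exactly zero. Lesions are brighter than tissue by a fixed contrast
#' factor (default +40% of the mean tissue intensity) so that
#' segmentation is learnable by a small network.
#'
#' The generator is a pure function of `(profile, rng_seed)`: the same
#' arguments always return bit-identical volumes and masks, and the
#' caller's RNG state is left untouched.
#'
#' @param profile a [client_profile()].
#' @param rng_seed integer seed for this case.
#' @param case_id optional identifier stored in the result.
#' @param lesion_contrast lesion brightness as a multiple of the mean
#'   tissue intensity (default 1.4).
#' @param n_lesions optional exact lesion count overriding the Poisson
#'   draw (useful for degenerate test fixtures).
#' @return An object of class `synthetic_case`: a list with `case_id`,
#'   `volume` (3-D numeric array), `lesion_mask` and `brain_mask`
#'   (3-D integer arrays of 0/1).
#' @examples
#' p <- client_profile("a", 1, volume_shape = 24, noise_sigma = 0,
#'                     lesion_count_mean = 2, lesion_radius_range = c(2, 3))
#' case <- generate_case(p, rng_seed = 1)
#' sum(case$lesion_mask & !case$brain_mask)  # lesions inside brain: 0
#' @export
generate_case <- function(profile, rng_seed, case_id = NULL,
                          lesion_contrast = 1.4, n_lesions = NULL) {
  stopifnot(inherits(profile, "client_profile"))
  if (is.null(case_id)) case_id <- sprintf("%s_case_seed%d", profile$client_id, rng_seed)
  shape <- profile$volume_shape
  with_seed(rng_seed, {
    ctr <- (shape + 1) / 2
    semi <- profile$brain_radius_frac * (shape - 1) / 2
    g1 <- ((seq_len(shape[1]) - ctr[1]) / semi[1])^2
    g2 <- ((seq_len(shape[2]) - ctr[2]) / semi[2])^2
    g3 <- ((seq_len(shape[3]) - ctr[3]) / semi[3])^2
    dist2 <- outer(outer(g1, g2, `+`), g3, `+`)
    brain <- dist2 <= 1

    base <- tissue_field(shape)

    if (is.null(n_lesions)) n_lesions <- rpois(1, profile$lesion_count_mean)
    lesion <- array(FALSE, dim = shape)
    if (n_lesions > 0) {
      radii <- runif(n_lesions, profile$lesion_radius_range[1],
                     profile$lesion_radius_range[2])
      ax1 <- seq_len(shape[1]); ax2 <- seq_len(shape[2]); ax3 <- seq_len(shape[3])
      for (r in radii) {
        placed <- FALSE
        for (try in 1:100) {
          cand <- ctr + (2 * runif(3) - 1) * pmax(semi - r, 0)
          # sphere of radius r around cand must stay inside the ellipsoid
          margin <- sum(((cand - ctr) / pmax(semi - r, 1e-9))^2)
          if (margin <= 1) { placed <- TRUE; break }
        }
        if (!placed) {
          stopf("client '%s': could not place a lesion of radius %.2f inside the brain",
                profile$client_id, r)
        }
        d2 <- outer(outer((ax1 - cand[1])^2, (ax2 - cand[2])^2, `+`),
                    (ax3 - cand[3])^2, `+`)
        lesion <- lesion | (d2 <= r^2)
      }
      lesion <- lesion & brain
    }

    tissue_mean <- mean(base[brain])
    base[lesion] <- tissue_mean * lesion_contrast
    vol <- profile$intensity_scale * base + profile$intensity_offset
    if (profile$noise_sigma > 0) {
      vol <- vol + array(rnorm(prod(shape), sd = profile$noise_sigma), dim = shape)
    }
    vol[!brain] <- 0

    structure(list(
      case_id = case_id,
      volume = vol,
      lesion_mask = array(as.integer(lesion), dim = shape),
      brain_mask = array(as.integer(brain), dim = shape)
    ), class = "synthetic_case")
  })
}

#' @export
print.synthetic_case <- function(x, ...) {
  cat(sprintf("<synthetic_case '%s': %s voxels, %d brain, %d lesion (ratio %.4f)>\n",
              x$case_id, paste(dim(x$volume), collapse = "x"),
              sum(x$brain_mask), sum(x$lesion_mask),
              sum(x$lesion_mask) / max(1, sum(x$brain_mask))))
  invisible(x)
}

#' Generate a multi-client synthetic federation
#'
#' Produces `n_cases` cases for each client profile. Per-client seed
#' streams are derived from the master seed and the client's *position*
#' in the list, so regenerating one client is unaffected by changes to
#' another client's profile, and each case has its own independent seed.
#'
#' @param profiles list of [client_profile()] objects with distinct ids;
#'   at least two.
#' @param rng_seed master integer seed.
#' @return Named list (by client id) of lists of `synthetic_case`.
#' @export
generate_federation <- function(profiles, rng_seed) {
  if (length(profiles) < 2) stopf("a federation needs at least 2 client profiles")
  ids <- vapply(profiles, function(p) p$client_id, character(1))
  if (anyDuplicated(ids)) {
    stopf("duplicate client_id: %s", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  out <- vector("list", length(profiles))
  names(out) <- ids
  for (ci in seq_along(profiles)) {
    p <- profiles[[ci]]
    client_seed <- derive_seed(rng_seed, 1000 + ci)
    cases <- vector("list", p$n_cases)
    for (j in seq_len(p$n_cases)) {
      cases[[j]] <- generate_case(p, derive_seed(client_seed, j),
                                  case_id = sprintf("%s_%03d", p$client_id, j))
    }
    out[[ci]] <- cases
  }
  out
}

# The 48 axis-aligned symmetries of a cube are compositions of axis
# permutations and flips; the 90-degree rotations are the orientation-
# preserving half. Sampling a permutation (restricted to axes of equal
# length) plus independent flips covers all of them without interpolation,
# so masks stay binary and voxel multisets are preserved.
random_cube_symmetry <- function(patch_size) {
  perm <- 1:3
  if (patch_size[1] == patch_size[2] && patch_size[2] == patch_size[3]) {
    perm <- sample(3)
  } else if (patch_size[1] == patch_size[2]) {
    if (runif(1) < 0.5) perm <- c(2, 1, 3)
  } else if (patch_size[2] == patch_size[3]) {
    if (runif(1) < 0.5) perm <- c(1, 3, 2)
  } else if (patch_size[1] == patch_size[3]) {
    if (runif(1) < 0.5) perm <- c(3, 2, 1)
  }
  flips <- runif(3) < 0.5
  list(perm = perm, flips = flips)
}

apply_cube_symmetry <- function(a, sym) {
  a <- aperm(a, sym$perm)
  idx <- lapply(seq_len(3), function(ax) {
    if (sym$flips[ax]) rev(seq_len(dim(a)[ax])) else seq_len(dim(a)[ax])
  })
  a[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

#' Sample a (possibly augmented) training patch from a case
#'
#' Crops a patch at an offset drawn uniformly over all valid positions.
#' With `augment = TRUE`, a random composition of axis flips and
#' 90-degree-multiple rotations (restricted to axes of equal patch
#' length, so shapes are preserved) is applied identically to the volume
#' and the mask.
#'
#' @param case a `synthetic_case`, or any list with `volume` and
#'   `lesion_mask` 3-D arrays.
#' @param patch_size integer triple, each at most the volume shape.
#' @param augment logical; apply a random flip/rotation.
#' @param rng_seed optional seed; when `NULL` the current RNG stream is
#'   used (the training loop's behaviour).
#' @return List with `volume` and `mask` patch arrays of `patch_size`.
#' @export
sample_patch <- function(case, patch_size, augment = FALSE, rng_seed = NULL) {
  patch_size <- check_triple(patch_size, "patch_size")
  shape <- dim(case$volume)
  if (any(patch_size > shape)) {
    stopf("patch_size %s exceeds volume shape %s",
          paste(patch_size, collapse = "x"), paste(shape, collapse = "x"))
  }
  draw <- function() {
    off <- vapply(1:3, function(ax) {
      sample.int(shape[ax] - patch_size[ax] + 1L, 1L) - 1L
    }, integer(1))
    i1 <- off[1] + seq_len(patch_size[1])
    i2 <- off[2] + seq_len(patch_size[2])
    i3 <- off[3] + seq_len(patch_size[3])
    vol <- case$volume[i1, i2, i3, drop = FALSE]
    msk <- case$lesion_mask[i1, i2, i3, drop = FALSE]
    if (augment) {
      sym <- random_cube_symmetry(patch_size)
      vol <- apply_cube_symmetry(vol, sym)
      msk <- apply_cube_symmetry(msk, sym)
    }
    list(volume = vol, mask = msk)
  }
  if (is.null(rng_seed)) draw() else with_seed(rng_seed, draw())
}

#' Write a synthetic federation to disk as NIfTI pairs
#'
#' Each case is stored as `<case_id>_flair.nii.gz` (float intensities) and
#' `<case_id>_mask.nii.gz` (unsigned 8-bit 0/1), with one JSON manifest
#' per client listing its cases. Requires the RNifti package.
#'
#' @param federation named list of case lists, as from
#'   [generate_federation()].
#' @param dir output directory (created if needed); one subdirectory per
#'   client.
#' @return Invisibly, the manifest paths.
#' @export
write_federation_nifti <- function(federation, dir) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stopf("write_federation_nifti() requires the RNifti package")
  }
  manifests <- character(0)
  for (cid in names(federation)) {
    cdir <- file.path(dir, cid)
    dir.create(cdir, recursive = TRUE, showWarnings = FALSE)
    entries <- lapply(federation[[cid]], function(case) {
      vf <- file.path(cdir, paste0(case$case_id, "_flair.nii.gz"))
      mf <- file.path(cdir, paste0(case$case_id, "_mask.nii.gz"))
      RNifti::writeNifti(case$volume, vf)
      RNifti::writeNifti(array(as.integer(case$lesion_mask), dim(case$lesion_mask)),
                         mf, datatype = "uint8")
      list(case_id = case$case_id, volume = basename(vf), mask = basename(mf))
    })
    mpath <- file.path(cdir, "manifest.json")
    jsonlite::write_json(list(client_id = cid, cases = entries), mpath,
                         auto_unbox = TRUE, pretty = TRUE)
    manifests <- c(manifests, mpath)
  }
  invisible(manifests)
}

#' Read a federation previously written with [write_federation_nifti()]
#'
#' Brain masks are reconstructed as the nonzero support of the intensity
#' volume (background is exactly zero by construction).
#'
#' @param dir directory containing one subdirectory per client.
#' @return Named list of case lists.
#' @export
read_federation_nifti <- function(dir) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stopf("read_federation_nifti() requires the RNifti package")
  }
  cdirs <- list.dirs(dir, recursive = FALSE)
  out <- list()
  for (cdir in cdirs) {
    man <- jsonlite::read_json(file.path(cdir, "manifest.json"), simplifyVector = FALSE)
    cases <- lapply(man$cases, function(e) {
      vol <- RNifti::readNifti(file.path(cdir, e$volume))
      vol <- array(as.numeric(vol), dim = dim(vol))
      msk <- RNifti::readNifti(file.path(cdir, e$mask))
      msk <- array(as.integer(msk), dim = dim(msk))
      structure(list(case_id = e$case_id, volume = vol, lesion_mask = msk,
                     brain_mask = array(as.integer(vol != 0), dim = dim(vol))),
                class = "synthetic_case")
    })
    out[[man$client_id]] <- cases
  }
  out
}

#' Build client profiles from a configuration list or file
#'
#' Accepts a YAML or JSON file path, or an already-parsed list, holding a
#' list of client profile fields (as accepted by [client_profile()]).
#'
#' @param config path to a `.yaml`/`.yml`/`.json` file, or a list.
#' @return List of `client_profile` objects.
#' @export
profiles_from_config <- function(config) {
  if (is.character(config)) {
    config <- read_config_file(config)
  }
  entries <- if (!is.null(config$clients)) config$clients else config
  lapply(entries, function(e) do.call(client_profile, e))
}

read_config_file <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stopf("reading YAML configs requires the yaml package")
    }
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                        simplifyMatrix = FALSE)
  } else {
    stopf("config file must be .yaml, .yml or .json: %s", path)
  }
}
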