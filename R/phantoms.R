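# Seeded synthetic brain phantoms: nested deformed ellipsoidal regions
# rendered in two artificial "modalities", with known smooth ground-truth
# displacement fields. These stand in for multi-modal whole-brain data in
# every test and experiment; all generators are pure functions of their
# seeds.

#' Specification of a phantom volume
#'
#' @param shape Voxel dimensions (each >= 16 so the networks' four
#'   downsamplings stay valid).
#' @param n_regions Number K of foreground regions (nested shells), >= 2.
#' @param deform_amplitude Maximum ground-truth displacement magnitude in
#'   voxels (0 disables deformation).
#' @param deform_smoothness Gaussian sigma (voxels) of the ground-truth
#'   field (default calibrated to the default 48-voxel grid; see the
#'   methods vignette). Large sigma relative to the amplitude keeps
#'   fields folding-free.
#' @param noise_sd Additive Gaussian intensity noise of the renderings.
#' @param seed Integer seed; all phantom randomness derives from it.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(shape = c(48, 48, 48), n_regions = 4,
                         deform_amplitude = 3, deform_smoothness = 18,
                         noise_sd = 0.02, seed = 0) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3, n_regions >= 2, deform_amplitude >= 0,
            deform_smoothness > 0, noise_sd >= 0)
  if (any(shape < 16)) stop("every shape component must be at least 16")
  structure(list(shape = shape, n_regions = as.integer(n_regions),
                 deform_amplitude = deform_amplitude,
                 deform_smoothness = deform_smoothness,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Intensity rendering preset for one "modality"
#'
#' Two presets whose per-region means are not monotonically related mimic a
#' genuine modality gap: no global intensity mapping aligns the renderings.
#'
#' @param means Per-region mean intensities, length K + 1 (background first).
#' @param texture_scale Amplitude of band-limited texture.
#' @param bias_field_strength Amplitude of the smooth multiplicative bias.
#' @param noise_sd Additive Gaussian noise sd.
#' @return A `modality_preset` list.
#' @export
modality_preset <- function(means, texture_scale = 0.05,
                            bias_field_strength = 0.15, noise_sd = 0.02) {
  stopifnot(texture_scale >= 0, bias_field_strength >= 0, noise_sd >= 0)
  structure(list(means = as.numeric(means), texture_scale = texture_scale,
                 bias_field_strength = bias_field_strength,
                 noise_sd = noise_sd),
            class = "modality_preset")
}

#' Default pair of modality presets
#'
#' Preset A orders region means monotonically with the label index; preset B
#' permutes them (and inverts the background), so the two renderings of the
#' same labels have non-monotonically related region intensities.
#'
#' @param K Number of foreground regions.
#' @return List with elements `A` and `B`.
#' @export
default_presets <- function(K) {
  a <- c(0.05, seq(0.35, 0.9, length.out = K))
  fg <- seq(0.3, 0.95, length.out = K)
  # swap neighbours so the ordering cannot be reproduced by any monotone map
  perm <- seq_len(K)
  for (i in seq(1, K - 1, by = 2)) perm[c(i, i + 1)] <- perm[c(i + 1, i)]
  b <- c(0.55, fg[perm])
  list(A = modality_preset(a), B = modality_preset(b, texture_scale = 0.08,
                                                   bias_field_strength = 0.2))
}

# separable Gaussian smoothing of a 3D array, truncated-renormalized kernels
gaussian_smooth3 <- function(x, sigma) {
  if (sigma <= 0) return(x)
  d <- dim(x)
  kmat <- function(n) {
    i <- seq_len(n)
    k <- exp(-outer(i, i, `-`)^2 / (2 * sigma^2))
    k / rowSums(k)
  }
  x <- array(kmat(d[1]) %*% matrix(x, d[1]), d)
  x <- aperm(array(kmat(d[2]) %*% matrix(aperm(x, c(2, 1, 3)), d[2]),
                   d[c(2, 1, 3)]), c(2, 1, 3))
  aperm(array(kmat(d[3]) %*% matrix(aperm(x, c(3, 1, 2)), d[3]),
              d[c(3, 1, 2)]), c(2, 3, 1))
}

#' Generate a nested-region label phantom
#'
#' A brain-like connected foreground built from randomly deformed concentric
#' ellipsoids: a thin outer cortex-like shell (label K), a mid shell below it
#' (label K - 1, when K >= 3), an interior bulk (label 1) and, for K >= 4,
#' small ellipsoidal "nucleus" blobs (labels 2..K-2) embedded in the bulk.
#' Structure thicknesses are a small number of voxels, so modest
#' misalignments already cost substantial overlap - mirroring the overlap
#' headroom that affinely pre-aligned whole-brain data exhibits.
#'
#' @param spec A [phantom_spec()].
#' @return 3D integer label array with value set `{0..K}`.
#' @export
make_label_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  K <- spec$n_regions
  d <- spec$shape
  if (min(d) < 6 * K) {
    stop(sprintf(
      "shape (%s) too small for %d nested regions; need min dim >= %d",
      paste(d, collapse = "x"), K, 6 * K))
  }
  with_seed(spec$seed, {
    centre <- d / 2 + stats::runif(3, -0.03, 0.03) * d
    semi <- 0.42 * d * (1 + stats::runif(3, -0.08, 0.08))
    co <- lapply(1:3, function(a) (seq_len(d[a]) - centre[a]) / semi[a])
    u <- sqrt(outer(outer(co[[1]]^2, co[[2]]^2, `+`), co[[3]]^2, `+`))
    eps <- gaussian_smooth3(array(stats::rnorm(prod(d)), d), min(d) / 8)
    eps <- eps / stats::sd(eps) * 0.05
    u <- pmax(u + eps, 0)
    # shells: cortex-like outer band and (K >= 3) a mid band beneath it.
    # Thicknesses are fixed in voxels (like cortical thickness in mm), so
    # misalignment sensitivity does not wash out on larger grids.
    shell_th <- (if (K == 2) 3 else 2) / mean(semi)
    lab <- array(0L, d)
    lab[u < 1] <- 1L
    if (K >= 3) lab[u < 1 & u >= 1 - 2 * shell_th] <- K - 1L
    lab[u < 1 & u >= 1 - shell_th] <- K
    # interior blobs (labels 2..K-2): nucleus-like structures at consistent
    # "anatomical" directions (small seeded jitter), as real nuclei occupy
    # consistent positions across individuals
    n_blob <- max(0L, K - 3L)
    if (n_blob > 0) {
      canon <- matrix(c(1, 0.6, -0.4,
                        -0.8, -0.5, 0.6,
                        0.2, -1, -0.6,
                        -0.4, 0.9, 0.5), ncol = 3, byrow = TRUE)
      dirs <- canon[((seq_len(n_blob) - 1L) %% 4L) + 1L, , drop = FALSE] +
        matrix(stats::rnorm(3 * n_blob, sd = 0.08), ncol = 3)
      dirs <- dirs / sqrt(rowSums(dirs^2))
      xyz <- lapply(1:3, function(a) slice.index(u, a))
      for (j in seq_len(n_blob)) {
        bc <- centre + dirs[j, ] * semi * (0.3 + 0.1 * (j %% 2)) *
          stats::runif(1, 0.92, 1.08)
        br <- rep(3 + 0.5 * (j %% 2), 3) * stats::runif(1, 0.9, 1.1)
        v <- sqrt(((xyz[[1]] - bc[1]) / br[1])^2 +
                  ((xyz[[2]] - bc[2]) / br[2])^2 +
                  ((xyz[[3]] - bc[3]) / br[3])^2)
        lab[v < 1 & lab == 1L] <- 1L + j
      }
    }
    storage.mode(lab) <- "integer"
    dim(lab) <- d
    present <- sort(unique(as.vector(lab)))
    if (!identical(present, 0:K)) {
      stop("phantom generation failed to produce all regions; enlarge shape")
    }
    lab
  })
}

#' Render a label phantom in one modality
#'
#' Intensity = per-region mean, times a smooth multiplicative bias field,
#' plus band-limited texture and Gaussian noise, clipped to [0, 1].
#'
#' @param labels 3D integer label array with values `0..K`.
#' @param preset A [modality_preset()] with at least K + 1 means.
#' @param seed Integer seed for bias, texture and noise.
#' @return 3D intensity array in `[0, 1]`.
#' @export
render_modality <- function(labels, preset, seed = 0) {
  stopifnot(inherits(preset, "modality_preset"))
  K <- max(labels)
  if (length(preset$means) < K + 1) {
    stop(sprintf("preset supplies %d means but labels need %d",
                 length(preset$means), K + 1))
  }
  d <- dim(labels)
  with_seed(seed, {
    img <- array(preset$means[labels + 1L], d)
    if (preset$bias_field_strength > 0) {
      b <- gaussian_smooth3(array(stats::rnorm(prod(d)), d), min(d) / 4)
      b <- (b - mean(b)) / stats::sd(b)
      img <- img * (1 + preset$bias_field_strength * b)
    }
    if (preset$texture_scale > 0) {
      tx <- gaussian_smooth3(array(stats::rnorm(prod(d)), d), 1.5)
      tx <- (tx - mean(tx)) / stats::sd(tx)
      img <- img + preset$texture_scale * tx
    }
    if (preset$noise_sd > 0) {
      img <- img + array(stats::rnorm(prod(d), sd = preset$noise_sd), d)
    }
    pmin(pmax(img, 0), 1)
  })
}

#' Generate a smooth random displacement field
#'
#' Independent Gaussian-smoothed random fields per axis, rescaled so the
#' maximum offset magnitude equals `amplitude` exactly. For
#' `amplitude / smoothness` well below 1 the resulting deformation is
#' folding-free.
#'
#' @param shape Spatial dims.
#' @param amplitude Maximum displacement magnitude in voxels (>= 0).
#' @param smoothness Gaussian sigma in voxels.
#' @param seed Integer seed.
#' @return 4D array `(shape, 3)`.
#' @export
make_smooth_displacement <- function(shape, amplitude, smoothness, seed = 0) {
  stopifnot(amplitude >= 0, length(shape) == 3)
  shape <- as.integer(shape)
  if (amplitude == 0) return(zero_field(shape))
  with_seed(seed, {
    f <- array(0, c(shape, 3))
    for (a in 1:3) {
      f[, , , a] <- gaussian_smooth3(array(stats::rnorm(prod(shape)), shape),
                                     smoothness)
    }
    mag <- sqrt(f[, , , 1]^2 + f[, , , 2]^2 + f[, , , 3]^2)
    f * (amplitude / max(mag))
  })
}

#' Generate a registration pair with ground truth
#'
#' The fixed labels come from [make_label_phantom()]; the moving labels are
#' the fixed ones warped (nearest neighbour) by a ground-truth smooth field;
#' each side is rendered in its own modality. Under the warp convention
#' `W(M, phi)[p] = M[p + phi[p]]`, the field that registers the moving image
#' back onto the fixed one is approximately the negated truth field.
#'
#' @param spec A [phantom_spec()].
#' @param preset_fixed,preset_moving Modality presets for the two renderings.
#' @return List with `fixed`, `fixed_labels`, `moving`, `moving_labels`,
#'   `truth` (the 4D ground-truth field) and `spec`.
#' @export
make_pair <- function(spec, preset_fixed, preset_moving) {
  fixed_labels <- make_label_phantom(spec)
  truth <- make_smooth_displacement(spec$shape, spec$deform_amplitude,
                                    spec$deform_smoothness,
                                    seed = spec$seed + 1009L)
  moving_labels <- warp_nearest(fixed_labels, truth)
  pf <- preset_fixed; pm <- preset_moving
  pf$noise_sd <- spec$noise_sd
  pm$noise_sd <- spec$noise_sd
  list(fixed = render_modality(fixed_labels, pf, seed = spec$seed + 11L),
       fixed_labels = fixed_labels,
       moving = render_modality(moving_labels, pm, seed = spec$seed + 12L),
       moving_labels = moving_labels,
       truth = truth, spec = spec)
}
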