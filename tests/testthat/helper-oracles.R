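# Shared fixtures and independent oracles, built in code at test time.

# brute-force SDR: exhaustive minimum over the boundary voxels of each
# voxel's own region (vectorized over the region)
brute_sdr <- function(labels, spacing = c(1, 1, 1)) {
  d <- dim(labels)
  b <- region_boundary(labels)
  out <- array(0, d)
  idx <- which(array(TRUE, d), arr.ind = TRUE)
  for (r in sort(unique(as.vector(labels)))) {
    inr <- as.vector(labels == r)
    sites <- which(b & labels == r, arr.ind = TRUE)
    pts <- idx[inr, , drop = FALSE]
    d2 <- outer(pts[, 1] * spacing[1], sites[, 1] * spacing[1], `-`)^2 +
      outer(pts[, 2] * spacing[2], sites[, 2] * spacing[2], `-`)^2 +
      outer(pts[, 3] * spacing[3], sites[, 3] * spacing[3], `-`)^2
    out[inr] <- sqrt(apply(d2, 1, min))
  }
  out
}

# random small label volume (always contains at least two labels)
random_labels <- function(seed, max_dim = 16, k_max = 3) {
  set.seed(seed)
  d <- sample(5:max_dim, 3, replace = TRUE)
  k <- sample(1:k_max, 1)
  repeat {
    lab <- array(sample(0:k, prod(d), replace = TRUE), d)
    if (length(unique(as.vector(lab))) >= 2) break
  }
  lab
}

# small nested phantom used across tests
tiny_spec <- function(seed = 7, shape = c(32, 32, 32), K = 3,
                      amplitude = 3, smoothness = 10) {
  phantom_spec(shape = shape, n_regions = K, deform_amplitude = amplitude,
               deform_smoothness = smoothness, seed = seed)
}

# central-difference numerical gradient of f at x
num_grad <- function(f, x, eps = 1e-5) {
  g <- x
  for (i in seq_along(x)) {
    x1 <- x; x1[i] <- x1[i] + eps
    x2 <- x; x2[i] <- x2[i] - eps
    g[i] <- (f(x1) - f(x2)) / (2 * eps)
  }
  g
}

# strip distance_rep attributes down to a plain array
bare <- function(x) {
  a <- unclass(x)
  attributes(a) <- list(dim = dim(a))
  a
}

# direct-loop double-precision 3x3x3 convolution (padding 1): the reference
# the GEMM kernel is checked against
brute_conv3 <- function(x, w, b) {
  d <- dim(x)
  co <- dim(w)[5]
  out <- array(0, c(d[1:3], co))
  for (o in seq_len(co)) {
    acc <- array(b[o], d[1:3])
    for (ci in seq_len(d[4])) {
      for (kz in -1:1) for (ky in -1:1) for (kx in -1:1) {
        wv <- w[kx + 2, ky + 2, kz + 2, ci, o]
        if (wv == 0) next
        sh <- array(0, d[1:3])
        xs <- max(1, 1 + kx):min(d[1], d[1] + kx)
        ys <- max(1, 1 + ky):min(d[2], d[2] + ky)
        zs <- max(1, 1 + kz):min(d[3], d[3] + kz)
        sh[xs - kx, ys - ky, zs - kz] <- x[xs, ys, zs, ci]
        acc <- acc + wv * sh
      }
    }
    out[, , , o] <- acc
  }
  out
}
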