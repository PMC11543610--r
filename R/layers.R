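# Differentiable layer primitives for 4D tensors laid out (nx, ny, nz, C).
# Each *_fwd returns what its *_bwd needs; gradients are hand-derived and
# checked against finite differences in the test suite.

# run code with a temporary RNG state seeded at `seed`
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else {
      suppressWarnings(rm(".Random.seed", envir = globalenv()))
    }
  })
  set.seed(seed)
  code
}

as_tensor4 <- function(x) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  x
}

# ---- 3x3x3 convolution, padding 1 (C++ im2col + GEMM) ----------------------

# convolutions default to the single-precision GEMM path; set
# options(esdreg.conv_single = FALSE) for exact double precision
conv_single <- function() isTRUE(getOption("esdreg.conv_single", TRUE))

nn_conv3_fwd <- function(x, w, b) .conv3_fwd(x, w, b, dim(x), conv_single())

nn_conv3_bwd <- function(x, w, dout, want_dx = TRUE) {
  .conv3_bwd(x, w, dout, dim(x), dim(w)[5], want_dx, conv_single())
}

# ---- 1x1x1 convolution (plain GEMM over channels) --------------------------

nn_conv1_fwd <- function(x, w, b) {
  d <- dim(x)
  n <- prod(d[1:3])
  out <- matrix(x, n, d[4]) %*% w
  out <- out + rep(b, each = n)
  dim(out) <- c(d[1:3], ncol(w))
  out
}

nn_conv1_bwd <- function(x, w, dout) {
  d <- dim(x)
  n <- prod(d[1:3])
  dm <- matrix(dout, n, ncol(w))
  xm <- matrix(x, n, d[4])
  dx <- dm %*% t(w)
  dim(dx) <- d
  list(dx = dx, dw = crossprod(xm, dm), db = colSums(dm))
}

# ---- transposed convolution, kernel 2 stride 2 (upsampling) ----------------
# weight dim (2,2,2,Cin,Cout); every output voxel receives exactly one term,
# so the operation is 8 channel-mixing GEMMs plus a strided scatter.

deconv_wmat <- function(w) {
  ci <- dim(w)[4]
  matrix(aperm(w, c(4, 1, 2, 3, 5)), nrow = ci)
}

nn_deconv2_fwd <- function(x, w, b) {
  d <- dim(x)
  co <- dim(w)[5]
  n <- prod(d[1:3])
  y <- matrix(x, n, d[4]) %*% deconv_wmat(w) # n x (8*co)
  out <- array(0, c(2L * d[1:3], co))
  i1 <- seq(1L, 2L * d[1], 2L); i2 <- seq(1L, 2L * d[2], 2L)
  i3 <- seq(1L, 2L * d[3], 2L)
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    k <- dx + 2L * dy + 4L * dz
    cols <- k + 8L * (seq_len(co) - 1L) + 1L
    out[i1 + dx, i2 + dy, i3 + dz, ] <- array(y[, cols], c(d[1:3], co))
  }
  out + rep(b, each = 8L * n)
}

nn_deconv2_bwd <- function(x, w, dout) {
  d <- dim(x)
  ci <- d[4]
  co <- dim(w)[5]
  n <- prod(d[1:3])
  i1 <- seq(1L, 2L * d[1], 2L); i2 <- seq(1L, 2L * d[2], 2L)
  i3 <- seq(1L, 2L * d[3], 2L)
  dy8 <- matrix(0, n, 8L * co)
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    k <- dx + 2L * dy + 4L * dz
    cols <- k + 8L * (seq_len(co) - 1L) + 1L
    dy8[, cols] <- matrix(dout[i1 + dx, i2 + dy, i3 + dz, ], n, co)
  }
  wm <- deconv_wmat(w)
  dx <- dy8 %*% t(wm)
  dim(dx) <- d
  dwm <- crossprod(matrix(x, n, ci), dy8) # ci x 8co
  dw <- aperm(array(dwm, c(ci, 2, 2, 2, co)), c(2, 3, 4, 1, 5))
  db <- colSums(matrix(dout, 8L * n, co))
  list(dx = dx, dw = dw, db = db)
}

# ---- 2x2x2 max pooling -----------------------------------------------------

nn_maxpool2_fwd <- function(x) .maxpool2_fwd(x, dim(x))

nn_maxpool2_bwd <- function(cache, dout) {
  .maxpool2_bwd(cache$idx, dout, cache$dims)
}

# ---- group normalization (batch of one) ------------------------------------

gn_ngroups <- function(channels, groups = 8L) {
  g <- min(groups, channels)
  while (channels %% g != 0L) g <- g - 1L
  g
}

nn_gn_fwd <- function(x, gamma, beta, groups = 8L, eps = 1e-5) {
  g <- gn_ngroups(dim(x)[4], groups)
  res <- .gn_fwd(x, gamma, beta, dim(x), g, eps)
  res$x <- x
  res
}

nn_gn_bwd <- function(cache, gamma, dout) {
  .gn_bwd(cache$x, gamma, dout, cache$mu, cache$istd, cache$dims, cache$g)
}

# ---- activations -----------------------------------------------------------

act_code <- c(relu = 0L, lrelu = 1L, sigmoid = 2L)

nn_act_fwd <- function(x, act, slope = 0.01) {
  if (act == "none") return(x)
  .act_fwd(x, act_code[[act]], slope)
}

nn_act_bwd <- function(x, out, act, dout, slope = 0.01) {
  if (act == "none") return(dout)
  ref <- if (act == "sigmoid") out else x
  .act_bwd(ref, dout, act_code[[act]], slope)
}

# channel softmax over the 4th dimension
nn_softmax_fwd <- function(x) {
  d <- dim(x)
  n <- prod(d[1:3])
  xm <- matrix(x, n, d[4])
  mx <- xm[, 1]
  for (c in seq_len(d[4])[-1]) mx <- pmax(mx, xm[, c])
  e <- exp(xm - mx)
  p <- e / rowSums(e)
  dim(p) <- d
  p
}

nn_softmax_bwd <- function(p, dp) {
  d <- dim(p)
  n <- prod(d[1:3])
  pm <- matrix(p, n, d[4])
  dm <- matrix(dp, n, d[4])
  dx <- pm * (dm - rowSums(dm * pm))
  dim(dx) <- d
  dx
}
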