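test_that("parameter counts are pure functions of the configs", {
  # regression guard against accidental architecture drift
  expect_identical(net_param_count(build_feature_net(feature_net_config())),
                   5647857L)
  expect_identical(net_param_count(build_reg_net(reg_net_config())), 216451L)
  expect_identical(net_param_count(build_seg_net(seg_net_config(5))), 879525L)
  # same seed, same weights; different seed, different weights
  a <- build_feature_net(feature_net_config(c(4, 4, 8, 8, 8), seed = 1))
  b <- build_feature_net(feature_net_config(c(4, 4, 8, 8, 8), seed = 1))
  expect_identical(a$params, b$params)
  c3 <- build_feature_net(feature_net_config(c(4, 4, 8, 8, 8), seed = 2))
  expect_false(identical(a$params, c3$params))
})

test_that("feature network maps volumes to (0, 1) at full resolution", {
  net <- build_feature_net(feature_net_config(c(4, 4, 8, 8, 8), seed = 1))
  x <- array(runif(16^3), c(16, 16, 16))
  out <- esdreg:::net_predict(net, x)
  expect_equal(dim(out), c(16, 16, 16, 1))
  expect_true(all(out > 0 & out < 1))
  # different inputs give different outputs
  y <- array(runif(16^3), c(16, 16, 16))
  expect_false(identical(esdreg:::net_predict(net, y), out))
})

test_that("invalid input shapes are rejected with the divisibility stated", {
  net <- build_feature_net(feature_net_config(c(4, 4, 8, 8, 8), seed = 1))
  expect_error(esdreg:::net_predict(net, array(0, c(20, 20, 20))),
               "divisible by 16")
  rn <- build_reg_net(reg_net_config(c(4, 8, 8, 8), seed = 1))
  expect_error(esdreg:::net_predict(rn, array(0, c(16, 16, 16, 1))),
               "channel")
})

test_that("registration network starts at the identity and is asymmetric", {
  rn <- build_reg_net(reg_net_config(c(4, 8, 8, 8), seed = 1))
  z <- array(runif(2 * 16^3), c(16, 16, 16, 2))
  phi <- esdreg:::net_predict(rn, z)
  expect_equal(dim(phi), c(16, 16, 16, 3))
  expect_equal(max(abs(phi)), 0) # zero-initialized head: identity transform
  # perturb the head: swapped input order must change the field
  set.seed(9)
  rn$params$head_w[] <- rnorm(length(rn$params$head_w), sd = 0.05)
  zswap <- z[, , , 2:1]
  f1 <- esdreg:::net_predict(rn, z)
  f2 <- esdreg:::net_predict(rn, zswap)
  expect_gt(max(abs(f1 - f2)), 0)
})

test_that("segmentation network emits per-voxel probability simplexes", {
  expect_error(seg_net_config(1), "at least 2")
  sn <- build_seg_net(seg_net_config(5, c(2, 4, 4, 8), seed = 1))
  p <- esdreg:::net_predict(sn, array(runif(16^3), c(16, 16, 16)))
  expect_equal(dim(p), c(16, 16, 16, 5))
  expect_equal(apply(p, 1:3, sum), array(1, c(16, 16, 16)), tolerance = 1e-12)
  lab <- max.col(matrix(p, 16^3, 5)) - 1L
  expect_true(all(lab %in% 0:4))
})

test_that("convolution kernel matches a direct-loop double oracle", {
  set.seed(8)
  d <- c(5, 4, 4)
  x <- array(rnorm(prod(d) * 2), c(d, 2))
  w <- array(rnorm(27 * 2 * 3), c(3, 3, 3, 2, 3))
  b <- rnorm(3)
  ref <- brute_conv3(x, w, b)
  got <- esdreg:::nn_conv3_fwd(x, w, b)
  expect_equal(got, ref, tolerance = 1e-5) # kernel runs in float32
  # analytic gradients vs finite differences of the double oracle
  tgt <- array(rnorm(length(ref)), dim(ref))
  dout <- 2 * (got - tgt)
  bw <- esdreg:::nn_conv3_bwd(x, w, dout)
  lw <- function(wv) sum((brute_conv3(x, array(wv, dim(w)), b) - tgt)^2)
  iw <- sample(length(w), 10)
  for (i in iw) {
    e <- 1e-6
    w1 <- as.vector(w); w1[i] <- w1[i] + e
    w2 <- as.vector(w); w2[i] <- w2[i] - e
    expect_equal(bw$dw[i], (lw(w1) - lw(w2)) / (2 * e), tolerance = 1e-3)
  }
  lx <- function(xv) sum((brute_conv3(array(xv, dim(x)), w, b) - tgt)^2)
  ix <- sample(length(x), 10)
  for (i in ix) {
    e <- 1e-6
    x1 <- as.vector(x); x1[i] <- x1[i] + e
    x2 <- as.vector(x); x2[i] <- x2[i] - e
    expect_equal(bw$dx[i], (lx(x1) - lx(x2)) / (2 * e), tolerance = 1e-3)
  }
})

test_that("backpropagated gradients match finite differences end to end", {
  withr::local_options(esdreg.conv_single = FALSE) # exact double conv path
  # tiny instances of all three architectures (group norm + ReLU,
  # no-norm + zero head, group norm + leaky ReLU + softmax)
  set.seed(5)
  x1 <- array(rnorm(16^3), c(16, 16, 16, 1))
  x2 <- array(rnorm(2 * 16^3), c(16, 16, 16, 2))
  nets <- list(
    list(net = build_feature_net(feature_net_config(c(2, 2, 2, 2, 2),
                                                    seed = 1)), x = x1),
    list(net = build_reg_net(reg_net_config(c(2, 3, 3, 3), seed = 2)),
         x = x2),
    list(net = build_seg_net(seg_net_config(3, c(2, 2, 3, 3), seed = 3)),
         x = x1))
  for (case in nets) {
    net <- case$net
    if (net$cfg$kind == "reg") { # leave the identity start for this check
      net$params$head_w[] <- rnorm(length(net$params$head_w), sd = 0.02)
    }
    fw <- esdreg:::unet_forward(net, case$x, want_cache = TRUE)
    tgt <- array(0.3, dim(fw$out))
    dout <- 2 * (fw$out - tgt)
    bw <- esdreg:::unet_backward(net, fw$cache, dout)
    lossf <- function(n) {
      o <- esdreg:::unet_forward(n, case$x)$out
      sum((o - tgt)^2)
    }
    for (nm in sample(names(net$params), 4)) {
      p <- net$params[[nm]]
      for (i in sample(length(p), min(2, length(p)))) {
        eps <- 1e-5
        n1 <- net; n1$params[[nm]][i] <- n1$params[[nm]][i] + eps
        n2 <- net; n2$params[[nm]][i] <- n2$params[[nm]][i] - eps
        num <- (lossf(n1) - lossf(n2)) / (2 * eps)
        expect_equal(bw$dparams[[nm]][i], num, tolerance = 1e-4,
                     label = sprintf("%s grad of %s[%d]", net$cfg$kind, nm, i))
      }
    }
  }
})

test_that("a network can overfit a single phantom", {
  # capacity / gradient-flow sanity: Huber regression loss on one small
  # phantom drops by an order of magnitude
  lab <- make_label_phantom(tiny_spec(1, shape = c(16, 16, 16), K = 2))
  img <- render_modality(lab, default_presets(2)$A, seed = 1)
  samples <- list(list(image = img, labels = lab))
  cfg <- train_config(epochs = 400, seed = 0)
  st <- pretrain_feature_net(samples, cfg,
    net = build_feature_net(feature_net_config(c(4, 8, 16, 32, 64), seed = 0)))
  h <- st$history$loss
  expect_lt(tail(h, 1), 0.1 * h[1])
  pred <- array(esdreg:::net_predict(st$net, img), dim(lab))
  gt <- bare(esdr_from_labels(lab))
  expect_lt(mean(abs(pred - gt)), 0.1)
})
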