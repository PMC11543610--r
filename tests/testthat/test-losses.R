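test_that("Huber loss takes its closed-form values", {
  one <- function(diff) array(diff, c(1, 1, 1))
  z <- array(0, c(1, 1, 1))
  expect_equal(huber_regression_loss(one(0), z), 0)
  expect_equal(huber_regression_loss(one(0.5), z), 0.125)
  expect_equal(huber_regression_loss(one(2), z), 1.5)
  expect_equal(huber_regression_loss(one(-2), z), 1.5)
  # delta switches the regimes
  expect_equal(huber_regression_loss(one(2), z, delta = 3), 2)
  expect_error(huber_regression_loss(one(1), z, delta = 0), "delta")
  expect_error(huber_regression_loss(array(0, c(2, 1, 1)), z), "shape")
})

test_that("Huber loss has a continuous first derivative at the switch", {
  z <- array(0, c(1, 1, 1))
  f <- function(x) huber_regression_loss(array(x, c(1, 1, 1)), z)
  eps <- 1e-5
  slope_below <- (f(1) - f(1 - eps)) / eps
  slope_above <- (f(1 + eps) - f(1)) / eps
  expect_equal(slope_below, slope_above, tolerance = 1e-4)
  expect_equal(slope_above, 1, tolerance = 1e-4)
})

test_that("registration similarity loss reduces to its closed forms", {
  d <- c(6, 6, 6)
  set.seed(1)
  e <- array(runif(prod(d)), d)
  f0 <- zero_field(d)
  expect_equal(registration_mse_loss(e, e, f0), 0)
  # constants are warp-invariant
  c1 <- array(0.8, d); c2 <- array(0.3, d)
  f <- array(rnorm(prod(d) * 3), c(d, 3))
  expect_equal(registration_mse_loss(c1, c2, f), 0.25, tolerance = 1e-12)
  # matching integer shift cancels on the interior (masked-mean oracle)
  ramp <- array(rep(seq_len(d[1]) / d[1], prod(d[2:3])), d)
  fs <- zero_field(d)
  fs[, , , 1] <- 1
  shifted <- ramp
  shifted[1:(d[1] - 1), , ] <- ramp[2:d[1], , ]
  w <- warp_linear(ramp, fs)
  expect_equal(w[1:(d[1] - 1), , ], shifted[1:(d[1] - 1), , ],
               tolerance = 1e-13)
})

test_that("smoothness loss matches hand-computed forward differences", {
  # constant (translation) fields cost nothing
  f <- zero_field(c(4, 4, 4))
  f[, , , 1] <- 3.2; f[, , , 2] <- -1; f[, , , 3] <- 0.5
  expect_equal(smoothness_loss(f), 0)
  # unit-gradient component: one of the nine component-axis pairs has mean
  # squared forward difference 1, the rest 0
  f <- zero_field(c(4, 4, 4))
  f[, , , 1] <- slice.index(f[, , , 1], 1)
  expect_equal(smoothness_loss(f), 1)
  # hand-computed on a small random field
  set.seed(2)
  f <- array(rnorm(3 * 4^3), c(4, 4, 4, 3))
  ref <- 0
  for (comp in 1:3) for (a in 1:3) {
    x <- f[, , , comp]
    dif <- switch(a,
      x[2:4, , ] - x[1:3, , ],
      x[, 2:4, ] - x[, 1:3, ],
      x[, , 2:4] - x[, , 1:3])
    ref <- ref + mean(dif^2)
  }
  expect_equal(smoothness_loss(f), ref, tolerance = 1e-12)
  # quadratic homogeneity
  expect_equal(smoothness_loss(2.5 * f), 2.5^2 * smoothness_loss(f),
               tolerance = 1e-12)
})

test_that("Dice score follows its definition and conventions", {
  d <- c(4, 2, 1)
  a <- array(0, d); b <- array(0, d)
  a[1:4] <- 1; b[3:6] <- 1 # |a| = 4, |b| = 4, overlap 2
  expect_equal(dice_score(a, b), 0.5)
  expect_equal(dice_score(a, a), 1)
  expect_equal(dice_score(a, b), dice_score(b, a))
  disj <- array(0, d); disj[7:8] <- 1
  expect_equal(dice_score(a, disj), 0)
  expect_equal(dice_score(array(0, d), array(0, d)), 1) # empty convention
})

test_that("auxiliary Dice loss averages foreground structures", {
  d <- c(8, 8, 8)
  set.seed(3)
  lab <- array(sample(0:2, prod(d), TRUE), d)
  f0 <- zero_field(d)
  expect_equal(auxiliary_dice_loss(lab, lab, f0, K = 2), 0,
               tolerance = 1e-3) # epsilon-smoothed denominators
  # disjoint structures give loss 1
  a <- array(0L, d); a[1:4, , ] <- 1L
  b <- array(0L, d); b[5:8, , ] <- 1L
  expect_equal(auxiliary_dice_loss(a, b, f0, K = 1), 1, tolerance = 1e-6)
  expect_error(auxiliary_dice_loss(a, b, f0, K = 0), "K")
})

test_that("segmentation Dice loss handles one-hot and uniform predictions", {
  d <- c(2, 2, 2)
  lab <- array(c(0L, 0L, 0L, 0L, 1L, 1L, 1L, 1L), d)
  onehot <- array(0, c(d, 2))
  onehot[, , , 1] <- (lab == 0) * 1
  onehot[, , , 2] <- (lab == 1) * 1
  expect_equal(segmentation_dice_loss(onehot, lab, K = 1), 0,
               tolerance = 1e-4)
  # uniform prediction over 2 classes on a half/half volume: soft Dice 0.5
  unif <- array(0.5, c(d, 2))
  expect_equal(segmentation_dice_loss(unif, lab, K = 1), 0.5,
               tolerance = 1e-4)
  expect_error(segmentation_dice_loss(unif, lab, K = 2), "channels")
})

test_that("total registration loss is the weighted sum", {
  parts <- c(regi = 0.2, smooth = 0.1, aus = 0.3)
  expect_equal(total_registration_loss(parts, loss_weights(1, 1, 1)), 0.6)
  expect_equal(total_registration_loss(parts, loss_weights(1, 1, 0)), 0.3)
  expect_equal(total_registration_loss(c(regi = 0, smooth = 0, aus = 0),
                                       loss_weights()), 0)
  expect_error(loss_weights(-1, 1, 1))
})

test_that("alignment signal: truth field beats zero field on phantom pairs", {
  sp <- tiny_spec(1, shape = c(32, 32, 32), K = 3, amplitude = 3)
  pr <- default_presets(3)
  p <- make_pair(sp, pr$A, pr$B)
  ef <- unclass(esdr_from_labels(p$fixed_labels))
  em <- unclass(esdr_from_labels(p$moving_labels))
  # registering the moving image back onto the fixed one undoes the truth
  # warp; its displacement is approximately the negated truth field
  expect_lt(registration_mse_loss(ef, em, -p$truth),
            registration_mse_loss(ef, em, zero_field(dim(ef))))
})

test_that("losses are non-negative on random inputs", {
  set.seed(4)
  d <- c(6, 6, 6)
  for (i in 1:5) {
    a <- array(runif(prod(d)), d)
    b <- array(runif(prod(d)), d)
    f <- array(rnorm(prod(d) * 3), c(d, 3))
    expect_gte(huber_regression_loss(a, b), 0)
    expect_gte(registration_mse_loss(a, b, f), 0)
    expect_gte(smoothness_loss(f), 0)
    la <- array(sample(0:2, prod(d), TRUE), d)
    lb <- array(sample(0:2, prod(d), TRUE), d)
    expect_gte(auxiliary_dice_loss(la, lb, f, 2), 0)
  }
})
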