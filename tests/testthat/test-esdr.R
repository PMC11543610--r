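test_that("region_boundary matches a brute-force neighbour scan", {
  # single-voxel region in a 5^3 volume: boundary is the voxel + 6 neighbours
  lab <- array(0L, c(5, 5, 5))
  lab[3, 3, 3] <- 1L
  b <- region_boundary(lab)
  expected <- array(FALSE, c(5, 5, 5))
  expected[3, 3, 3] <- TRUE
  for (o in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1))) {
    expected[3 + o[1], 3 + o[2], 3 + o[3]] <- TRUE
  }
  expect_identical(b, expected)

  # plane split: exactly the two voxel layers adjacent to the interface
  lab <- array(0L, c(4, 6, 5))
  lab[, 4:6, ] <- 1L
  b <- region_boundary(lab)
  expect_true(all(b[, 3:4, ]))
  expect_false(any(b[, c(1, 2, 5, 6), ]))

  # uniform volume: no interface anywhere
  expect_false(any(region_boundary(array(2L, c(4, 4, 4)))))

  # brute-force scan on random volumes
  for (seed in 1:5) {
    lab <- random_labels(seed, max_dim = 8)
    d <- dim(lab)
    ref <- array(FALSE, d)
    for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
      for (o in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                     c(0, 0, 1), c(0, 0, -1))) {
        q <- c(x, y, z) + o
        if (all(q >= 1) && all(q <= d) &&
            lab[q[1], q[2], q[3]] != lab[x, y, z]) {
          ref[x, y, z] <- TRUE
        }
      }
    }
    expect_identical(region_boundary(lab), ref)
  }
})

test_that("compute_sdr matches the exhaustive nearest-boundary oracle", {
  # 1x1x7 line example, unit spacing
  lab <- array(c(0L, 0L, 0L, 1L, 1L, 1L, 1L), c(7, 1, 1))
  sdr <- compute_sdr(lab)
  expect_equal(as.vector(sdr), c(2, 1, 0, 0, 1, 2, 3))
  expect_equal(as.vector(sdr), as.vector(brute_sdr(lab)))

  # doubling the spacing doubles every value
  sdr2 <- compute_sdr(lab, spacing = c(2, 2, 2))
  expect_equal(as.vector(sdr2), 2 * as.vector(sdr))

  for (seed in 1:10) {
    lab <- random_labels(seed + 100)
    expect_equal(bare(compute_sdr(lab)), brute_sdr(lab),
                 tolerance = 1e-12)
  }
  # anisotropic spacing
  for (seed in 1:3) {
    lab <- random_labels(seed + 200, max_dim = 9)
    sp <- c(0.5, 2, 1.25)
    expect_equal(bare(compute_sdr(lab, sp)), brute_sdr(lab, sp),
                 tolerance = 1e-12)
  }
})

test_that("compute_sdr rejects a uniform volume", {
  expect_error(compute_sdr(array(1L, c(4, 4, 4))), "uniform")
})

test_that("boundary voxels carry SDR 0 and ESDR 1", {
  lab <- make_label_phantom(tiny_spec(3, shape = c(24, 24, 24), K = 2))
  sdr <- compute_sdr(lab)
  b <- region_boundary(lab)
  expect_true(all(bare(sdr)[b] == 0))
  expect_true(all(bare(sdr)[!b] > 0))
  e <- compute_esdr(sdr)
  expect_true(all(bare(e)[b] == 1))
  expect_true(all(bare(e) > 0 & bare(e) <= 1))
})

test_that("exponential transform follows exp(-gamma * d) exactly", {
  lab <- random_labels(11)
  sdr <- compute_sdr(lab)
  for (g in c(0.5, 1, 2)) {
    expect_equal(bare(compute_esdr(sdr, g)), exp(-g * bare(sdr)),
                 tolerance = 1e-15)
  }
  line <- array(c(0L, 0L, 0L, 1L, 1L, 1L, 1L), c(7, 1, 1))
  e <- compute_esdr(compute_sdr(line), 1)
  expect_equal(as.vector(e)[5], exp(-1), tolerance = 1e-15) # SDR = 1 there
  expect_error(compute_esdr(sdr, gamma = 0), "gamma")
  expect_error(compute_esdr(sdr, gamma = -1), "gamma")
})

test_that("gamma rescales the distance at which ESDR crosses a threshold", {
  # solving exp(-gamma * d) = t gives d = -log(t) / gamma: doubling gamma
  # halves the crossing distance
  t0 <- 0.25
  d1 <- -log(t0) / 1
  d2 <- -log(t0) / 2
  expect_equal(d1 / d2, 2)
  lab <- array(rep(c(0L, 1L), each = 8 * 8 * 4), c(8, 8, 8))
  e1 <- bare(esdr_from_labels(lab, gamma = 1))
  e2 <- bare(esdr_from_labels(lab, gamma = 2))
  s <- bare(compute_sdr(lab))
  expect_true(max(abs(s[e1 >= t0])) >= max(abs(s[e2 >= t0])))
})

test_that("esdr_from_labels equals the composition and keeps its range", {
  lab <- make_label_phantom(tiny_spec(5, shape = c(24, 24, 24), K = 3))
  e <- esdr_from_labels(lab, gamma = 1.3)
  expect_equal(bare(e), bare(compute_esdr(compute_sdr(lab), 1.3)),
               tolerance = 1e-15)
  expect_true(all(bare(e) > 0 & bare(e) <= 1))
  # value-1 set is exactly the boundary mask
  expect_identical(bare(e) == 1, region_boundary(lab))
})

test_that("ESDR is strictly monotone in SDR within a region", {
  lab <- make_label_phantom(tiny_spec(9, shape = c(24, 24, 24), K = 2))
  sdr <- bare(compute_sdr(lab))
  e <- bare(esdr_from_labels(lab))
  r1 <- lab == 1
  o <- order(sdr[r1])
  expect_true(all(diff(e[r1][o]) <= 0))
  expect_true(all(diff(e[r1][o])[diff(sdr[r1][o]) > 0] < 0))
})

test_that("ESDR amplifies gradients at boundaries relative to the SDR", {
  # planar boundary: compare finite-difference magnitude across the
  # interface for ESDR vs the max-normalized negated SDR
  lab <- array(0L, c(16, 8, 8))
  lab[9:16, , ] <- 1L
  sdr <- bare(compute_sdr(lab))
  esdr <- exp(-sdr)
  nsdr <- 1 - sdr / max(sdr) # negated, normalized to [0, 1]
  line_e <- esdr[, 4, 4]
  line_n <- nsdr[, 4, 4]
  grad_at_boundary <- function(v) max(abs(diff(v)[7:9]))
  expect_gt(grad_at_boundary(line_e), grad_at_boundary(line_n))
})

test_that("ESDR depends on labels only, never on the rendering", {
  lab <- make_label_phantom(tiny_spec(2, shape = c(24, 24, 24), K = 3))
  pr <- default_presets(3)
  img_a <- render_modality(lab, pr$A, seed = 1)
  img_b <- render_modality(lab, pr$B, seed = 2)
  expect_false(isTRUE(all.equal(img_a, img_b)))
  expect_identical(esdr_from_labels(lab), esdr_from_labels(lab))
})

test_that("per-region ESDR stacks one channel per region", {
  lab <- random_labels(31)
  k <- length(unique(as.vector(lab)))
  e <- esdr_from_labels(lab, per_region = TRUE)
  expect_equal(dim(e), c(dim(lab), k))
  expect_true(all(bare(e) > 0 & bare(e) <= 1))
})
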