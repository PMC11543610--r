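# Training-loop behaviour on deliberately tiny problems: descent,
# determinism, branch wiring, inference plumbing. The scaled end-to-end
# recovery experiment lives in test-acceptance.R.

tiny_dataset <- function(K = 2, n = 2, shape = c(16, 16, 16)) {
  pr <- default_presets(K)
  pairs <- lapply(seq_len(n) - 1L, function(i) {
    make_pair(tiny_spec(i, shape = shape, K = K, amplitude = 2,
                        smoothness = 5), pr$A, pr$B)
  })
  samples <- unlist(lapply(pairs, function(p) list(
    list(image = p$fixed, labels = p$fixed_labels),
    list(image = p$moving, labels = p$moving_labels))), recursive = FALSE)
  list(pairs = pairs, samples = samples)
}

tiny_nets <- function(K = 2, seed = 0) {
  list(G = build_feature_net(feature_net_config(c(4, 4, 8, 8, 8), seed = seed)),
       S = build_seg_net(seg_net_config(K + 1, c(2, 4, 4, 8),
                                        seed = seed + 1)),
       R = build_reg_net(reg_net_config(c(4, 8, 8, 8), seed = seed + 2)))
}

test_that("pre-training descends and is bit-reproducible", {
  ds <- tiny_dataset()
  cfg <- train_config(epochs = 8, seed = 42)
  nets <- tiny_nets()

  g1 <- pretrain_feature_net(ds$samples, cfg, net = nets$G)
  g2 <- pretrain_feature_net(ds$samples, cfg, net = nets$G)
  expect_identical(g1$history$loss, g2$history$loss) # CPU determinism
  expect_identical(g1$net$params, g2$net$params)
  expect_lt(mean(tail(g1$history$loss, 4)), mean(head(g1$history$loss, 4)))

  s1 <- pretrain_seg_net(ds$samples, cfg, net = nets$S)
  s2 <- pretrain_seg_net(ds$samples, cfg, net = nets$S)
  expect_identical(s1$history$loss, s2$history$loss)
  expect_lt(mean(tail(s1$history$loss, 4)), mean(head(s1$history$loss, 4)))

  r1 <- pretrain_reg_net(ds$pairs, cfg, net = nets$R)
  r2 <- pretrain_reg_net(ds$pairs, cfg, net = nets$R)
  expect_identical(r1$history$loss, r2$history$loss)
  expect_lt(mean(tail(r1$history$loss, 4)), mean(head(r1$history$loss, 4)))

  expect_error(pretrain_feature_net(list(), cfg), "empty")
})

test_that("fine-tuning requires pre-trained states unless cold-started", {
  ds <- tiny_dataset()
  cfg <- train_config(epochs = 1, seed = 1)
  expect_error(finetune(list(G = NULL, S = NULL, R = NULL), ds$pairs, cfg),
               "cold_start")
  nets <- tiny_nets()
  ft <- finetune(nets, ds$pairs, cfg)
  expect_s3_class(ft$G, "esdreg_state")
  expect_true(all(c(1, 2) %in% ft$history$branch))
  # cold start runs from random initialization
  ft2 <- finetune(list(), ds$pairs, cfg, cold_start = TRUE)
  expect_s3_class(ft2$R, "esdreg_state")
  # determinism of the full fine-tuning loop
  ft3 <- finetune(nets, ds$pairs, cfg)
  expect_identical(ft$history$loss, ft3$history$loss)
})

test_that("registering an image onto itself stays near the identity", {
  ds <- tiny_dataset(n = 1)
  cfg <- train_config(epochs = 6, seed = 3)
  nets <- tiny_nets()
  gs <- pretrain_feature_net(ds$samples, cfg, net = nets$G)
  rs <- pretrain_reg_net(ds$pairs, cfg, net = nets$R)
  img <- ds$pairs[[1]]$fixed
  rr <- register_pair(gs, rs, img, img, ds$pairs[[1]]$fixed_labels)
  expect_equal(dim(rr$field), c(dim(img), 3))
  expect_equal(folding_fraction(rr$field), 0)
  expect_lt(mean(abs(rr$field)), 0.5)
  expect_identical(dim(rr$warped), dim(img))
  # field serialization round-trips bit-exactly
  tf <- tempfile(fileext = ".nii.gz")
  write_field(rr$field, tf)
  expect_identical(read_field(tf), rr$field)
})

test_that("segmentation inference emits labels and probabilities", {
  ds <- tiny_dataset(n = 1)
  nets <- tiny_nets()
  sg <- segment_image(nets$G, nets$S, ds$pairs[[1]]$fixed)
  expect_true(all(sg$labels %in% 0:2))
  expect_equal(apply(sg$probs, 1:3, sum), array(1, dim(sg$labels)),
               tolerance = 1e-12)
})

test_that("checkpoints round-trip losslessly", {
  ds <- tiny_dataset(n = 1)
  cfg <- train_config(epochs = 2, seed = 11)
  st <- pretrain_feature_net(ds$samples, cfg, net = tiny_nets()$G)
  tf <- tempfile(fileext = ".rds")
  save_checkpoint(st, tf)
  st2 <- load_checkpoint(tf)
  expect_identical(st2$net$params, st$net$params)
  expect_identical(st2$cfg, st$cfg)
  expect_identical(st2$stage, "pretrain-G")
})
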