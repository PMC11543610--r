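# End-to-end phantom experiment: build seeded multi-modal pairs, run the
# two-stage training scheme (or one of its ablations), and evaluate
# registration overlap, field folding and segmentation accuracy. Used by the
# test suite and the acceptance script so both measure exactly the same
# protocol.

#' Build a seeded multi-modal phantom dataset
#'
#' @param n_pairs Number of (fixed, moving) pairs; pair i uses seed
#'   `seed + i - 1`.
#' @param spec_template A [phantom_spec()] supplying shape, regions,
#'   deformation and noise settings.
#' @param presets Two modality presets (default [default_presets()]);
#'   fixed images render in `A`, moving in `B`.
#' @param seed Base seed.
#' @return List with `pairs` and `presets`.
#' @export
make_phantom_dataset <- function(n_pairs, spec_template = phantom_spec(),
                                 presets = NULL, seed = 0) {
  if (is.null(presets)) presets <- default_presets(spec_template$n_regions)
  pairs <- lapply(seq_len(n_pairs) - 1L, function(i) {
    sp <- spec_template
    sp$seed <- as.integer(seed + i)
    make_pair(sp, presets$A, presets$B)
  })
  list(pairs = pairs, presets = presets)
}

#' Run the coupled registration-segmentation experiment on phantoms
#'
#' Generates `n_pairs` multi-modal phantom pairs, pre-trains G, S and R on
#' ground-truth distance representations, fine-tunes the coupled branches,
#' then evaluates: registration Dice before/after, folding of predicted
#' fields, endpoint error against the (negated) ground-truth field,
#' held-out segmentation Dice, and the cross- vs within-modality
#' registration gap.
#'
#' @param n_pairs,spec_template,seed Passed to [make_phantom_dataset()].
#' @param epochs_g,epochs_s,epochs_r,epochs_ft Epochs for the three
#'   pre-training stages and for fine-tuning (the split of the overall
#'   budget between stages is a free choice; the distance regression of G
#'   converges fastest, the displacement regression of R slowest). The
#'   `"no_esdr"` ablation has no pre-training stage; it fine-tunes from
#'   random initialization for `cold_ft_factor * epochs_ft` epochs, roughly
#'   compute-matching the skipped pre-training.
#' @param cold_ft_factor Fine-tuning epoch multiplier of the cold-start
#'   ablation.
#' @param mode `"full"` (ESDR-guided two-stage), `"no_et"` (two-stage on the
#'   max-normalized SDR, no exponential transform), or `"no_esdr"`
#'   (cold-start fine-tuning only).
#' @param g_channels,r_channels,s_channels Stage widths of the three
#'   networks.
#' @param learning_rate,gamma,delta,weights Optimization settings (paper
#'   defaults).
#' @param n_holdout Extra phantoms (seeds after the training range) for
#'   held-out segmentation evaluation.
#' @param verbose Print stage progress.
#' @return List of metrics and trained states; see the methods vignette.
#' @export
run_coupled_experiment <- function(n_pairs = 8,
                                   spec_template = phantom_spec(),
                                   seed = 0,
                                   epochs_g = 10, epochs_s = 50,
                                   epochs_r = 80, epochs_ft = 4,
                                   cold_ft_factor = 3,
                                   mode = c("full", "no_et", "no_esdr"),
                                   g_channels = c(16, 32, 64, 128, 256),
                                   r_channels = c(16, 32, 32, 32),
                                   s_channels = c(8, 16, 32, 64),
                                   learning_rate = 1e-3, gamma = 1, delta = 1,
                                   weights = loss_weights(),
                                   n_holdout = 2, verbose = FALSE) {
  mode <- match.arg(mode)
  use_et <- mode != "no_et"
  K <- spec_template$n_regions
  ds <- make_phantom_dataset(n_pairs, spec_template, seed = seed)
  pairs <- ds$pairs
  samples <- unlist(lapply(pairs, function(p) list(
    list(image = p$fixed, labels = p$fixed_labels),
    list(image = p$moving, labels = p$moving_labels))), recursive = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))

  cfg_stage <- function(ep) {
    train_config(learning_rate = learning_rate, epochs = ep,
                 weights = weights, gamma = gamma, delta = delta, seed = seed)
  }
  cfg_ft <- train_config(learning_rate = learning_rate, epochs = epochs_ft,
                         weights = weights, gamma = gamma, delta = delta,
                         seed = seed)
  gcfg <- feature_net_config(g_channels, seed = seed)
  # raw distances are unbounded, so the no-exponential ablation swaps the
  # sigmoid head of G for a linear one
  if (mode == "no_et") gcfg$head$act <- "none"
  rcfg <- reg_net_config(r_channels, seed = seed + 2L)
  scfg <- seg_net_config(K + 1, s_channels, seed = seed + 1L)

  if (mode == "no_esdr") {
    say("cold-start fine-tuning (%d epochs)", cold_ft_factor * epochs_ft)
    ft <- finetune(list(G = build_feature_net(gcfg),
                        S = build_seg_net(scfg),
                        R = build_reg_net(rcfg)),
                   pairs, cfg_stage(cold_ft_factor * epochs_ft),
                   n_classes = K + 1)
  } else {
    say("pre-training G (%d epochs)", epochs_g)
    gs <- pretrain_feature_net(samples, cfg_stage(epochs_g),
                               net = build_feature_net(gcfg),
                               use_exponential = use_et)
    say("pre-training S (%d epochs)", epochs_s)
    ss <- pretrain_seg_net(samples, cfg_stage(epochs_s),
                           net = build_seg_net(scfg),
                           n_classes = K + 1, use_exponential = use_et)
    say("pre-training R (%d epochs)", epochs_r)
    rs <- pretrain_reg_net(pairs, cfg_stage(epochs_r),
                           net = build_reg_net(rcfg),
                           use_exponential = use_et)
    say("fine-tuning G-R / G-S (%d epochs)", epochs_ft)
    ft <- finetune(list(G = gs, S = ss, R = rs), pairs, cfg_ft,
                   n_classes = K + 1)
  }

  G <- get_net(ft$G); S <- get_net(ft$S); R <- get_net(ft$R)

  # --- registration evaluation on the training pairs ---
  structures <- seq_len(K)
  dsc0 <- dsc1 <- fold <- epe <- numeric(length(pairs))
  dsc_within <- numeric(length(pairs))
  for (i in seq_along(pairs)) {
    p <- pairs[[i]]
    dsc0[i] <- dsc_percent(p$moving_labels, p$fixed_labels,
                           structures)$mean_dsc
    rr <- register_pair(G, R, p$fixed, p$moving, p$moving_labels)
    dsc1[i] <- dsc_percent(rr$warped_labels, p$fixed_labels,
                           structures)$mean_dsc
    fold[i] <- folding_fraction(rr$field)
    epe[i] <- mean(sqrt(apply((rr$field + p$truth)^2, c(1, 2, 3), sum)))
    # within-modality control: moving geometry rendered in the fixed modality
    mv_a <- render_modality(p$moving_labels, ds$presets$A,
                            seed = p$spec$seed + 13L)
    ra <- register_pair(G, R, p$fixed, mv_a, p$moving_labels)
    dsc_within[i] <- dsc_percent(ra$warped_labels, p$fixed_labels,
                                 structures)$mean_dsc
  }

  # --- held-out segmentation evaluation (both modalities) ---
  seg_dsc <- numeric(0)
  for (h in seq_len(n_holdout)) {
    sp <- spec_template
    sp$seed <- as.integer(seed + 500L + h)
    lab <- make_label_phantom(sp)
    for (pr in list(ds$presets$A, ds$presets$B)) {
      img <- render_modality(lab, pr, seed = sp$seed + 17L)
      sg <- segment_image(G, S, img)
      seg_dsc <- c(seg_dsc, dsc_percent(sg$labels, lab, structures)$mean_dsc)
    }
  }

  list(mode = mode, n_pairs = n_pairs, shape = spec_template$shape,
       reg_dsc_unregistered = mean(dsc0), reg_dsc = mean(dsc1),
       reg_dsc_per_pair = dsc1, reg_dsc_unregistered_per_pair = dsc0,
       reg_dsc_within_modality = mean(dsc_within),
       folding_pct = mean(fold), endpoint_error = mean(epe),
       seg_dsc_holdout = mean(seg_dsc), seg_dsc_cases = seg_dsc,
       states = ft)
}
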