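# ESDR-guided two-stage training: separate pre-training of G (image ->
# ESDR), S (ESDR_gt -> labels) and R (paired ESDR_gt -> field), followed by
# iterative fine-tuning of the G-R and G-S branches on predicted ESDR.
# Optimization is Adam, batch size one, everything seeded and CPU-
# deterministic.

#' Training configuration
#'
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param epochs Number of passes over the dataset (default 160; scale down
#'   for quick experiments).
#' @param batch_size Fixed at 1; kept as a field for the run log.
#' @param weights [loss_weights()] for the registration objective.
#' @param gamma ESDR decay rate.
#' @param delta Huber switch point for the representation regression.
#' @param seed Integer seed controlling initialization and sample order.
#' @param finetune_alternation Optimization steps taken on one branch before
#'   switching to the other during fine-tuning.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-3, epochs = 160, batch_size = 1,
                         weights = loss_weights(), gamma = 1, delta = 1,
                         seed = 0, finetune_alternation = 1) {
  stopifnot(learning_rate > 0, epochs >= 1, gamma > 0, delta > 0,
            finetune_alternation >= 1)
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = 1L, weights = weights, gamma = gamma,
                 delta = delta, seed = as.integer(seed),
                 finetune_alternation = as.integer(finetune_alternation)),
            class = "train_config")
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (st$m[[nm]] / bc1) / (sqrt(st$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = st)
}

new_state <- function(net, opt, stage, epoch, history, cfg) {
  structure(list(net = net, opt = opt, stage = stage, epoch = epoch,
                 history = history, cfg = cfg), class = "esdreg_state")
}

#' @export
print.esdreg_state <- function(x, ...) {
  cat(sprintf("<esdreg train state: stage %s, epoch %d, final loss %.4g>\n",
              x$stage, x$epoch,
              if (nrow(x$history)) x$history$loss[nrow(x$history)] else NA))
  invisible(x)
}

get_net <- function(x) if (inherits(x, "esdreg_state")) x$net else x

# representation target used as supervision: the full scheme uses the ESDR;
# the "without exponential transform" ablation regresses the raw SDR (the
# feature network then needs a linear head, since distances are unbounded)
rep_from_labels <- function(labels, gamma = 1, use_exponential = TRUE) {
  sdr <- compute_sdr(labels)
  if (use_exponential) {
    unclass(compute_esdr(sdr, gamma))
  } else {
    unclass(sdr)
  }
}

epoch_order <- function(n, seed, epoch) with_seed(seed + 7919L * epoch, sample(n))

# ---- pre-training ----------------------------------------------------------

#' Pre-train the feature extraction network G
#'
#' Minimizes the Huber regression loss between G's prediction and the
#' ground-truth distance representation derived from each sample's labels.
#' Samples from all modalities are interleaved so the learned mapping is
#' modality-independent.
#'
#' @param samples List of samples, each a list with `image` (3D array) and
#'   `labels` (3D integer array).
#' @param cfg A [train_config()].
#' @param net Optional pre-built network (default: fresh
#'   [build_feature_net()] seeded from `cfg`).
#' @param use_exponential Use the ESDR (default); `FALSE` regresses a
#'   max-normalized SDR instead (ablation).
#' @return An `esdreg_state` with the trained network and loss history.
#' @export
pretrain_feature_net <- function(samples, cfg = train_config(), net = NULL,
                                 use_exponential = TRUE) {
  if (length(samples) == 0) stop("empty dataset")
  if (is.null(net)) net <- build_feature_net(feature_net_config(seed = cfg$seed))
  targets <- lapply(samples, function(s)
    rep_from_labels(s$labels, cfg$gamma, use_exponential))
  opt <- adam_init(net$params)
  hist <- list()
  for (ep in seq_len(cfg$epochs)) {
    for (i in epoch_order(length(samples), cfg$seed, ep)) {
      fw <- unet_forward(net, samples[[i]]$image, want_cache = TRUE)
      tgt <- targets[[i]]
      dim(tgt) <- dim(fw$out)
      loss <- huber_regression_loss(fw$out, tgt, cfg$delta)
      bw <- unet_backward(net, fw$cache, huber_grad(fw$out, tgt, cfg$delta))
      up <- adam_step(net$params, bw$dparams, opt, cfg$learning_rate)
      net$params <- up$params
      opt <- up$state
      hist[[length(hist) + 1L]] <- c(epoch = ep, loss = loss)
    }
  }
  new_state(net, opt, "pretrain-G", cfg$epochs, as_history(hist), cfg)
}

as_history <- function(hist) {
  if (length(hist) == 0) return(data.frame(epoch = integer(), loss = numeric()))
  df <- as.data.frame(do.call(rbind, hist))
  df$iter <- seq_len(nrow(df))
  df
}

#' Pre-train the segmentation network S
#'
#' S consumes the ground-truth distance representation of each sample and is
#' trained with the soft Dice loss against the sample's labels.
#'
#' @inheritParams pretrain_feature_net
#' @param n_classes Number of classes N (default: max label + 1).
#' @return An `esdreg_state`.
#' @export
pretrain_seg_net <- function(samples, cfg = train_config(), net = NULL,
                             n_classes = NULL, use_exponential = TRUE) {
  if (length(samples) == 0) stop("empty dataset")
  K <- max(vapply(samples, function(s) max(s$labels), numeric(1)))
  if (is.null(n_classes)) n_classes <- K + 1
  if (is.null(net)) {
    net <- build_seg_net(seg_net_config(n_classes, seed = cfg$seed + 1L))
  }
  inputs <- lapply(samples, function(s)
    rep_from_labels(s$labels, cfg$gamma, use_exponential))
  opt <- adam_init(net$params)
  hist <- list()
  for (ep in seq_len(cfg$epochs)) {
    for (i in epoch_order(length(samples), cfg$seed + 1L, ep)) {
      fw <- unet_forward(net, inputs[[i]], want_cache = TRUE)
      gt <- one_hot(samples[[i]]$labels, 0:(n_classes - 1))
      parts <- soft_dice_parts(gt, fw$out)
      bw <- unet_backward(net, fw$cache, soft_dice_grad(gt, fw$out, parts))
      up <- adam_step(net$params, bw$dparams, opt, cfg$learning_rate)
      net$params <- up$params
      opt <- up$state
      hist[[length(hist) + 1L]] <- c(epoch = ep, loss = parts$loss)
    }
  }
  new_state(net, opt, "pretrain-S", cfg$epochs, as_history(hist), cfg)
}

# forward + backward of the registration head given fixed/moving
# representations; returns losses, gradients for R and for the inputs
reg_branch_pass <- function(rnet, zf, zm, fixed_labels, moving_labels, K,
                            weights, delta = NULL, oh_f = NULL, oh_m = NULL) {
  d <- dim(zf)
  xin <- array(0, c(d[1:3], 2L))
  xin[, , , 1L] <- zf
  xin[, , , 2L] <- zm
  fw <- unet_forward(rnet, xin, want_cache = TRUE)
  phi <- fw$out
  zm4 <- zm
  dim(zm4) <- c(d[1:3], 1L)
  wzm <- .warp_linear(zm4, phi, dim(zm4))
  r <- as.vector(zf) - as.vector(wzm)
  l_regi <- mean(r * r)
  n <- length(r)
  dwzm <- array(-2 * r / n, dim(zm4))
  wb <- .warp_linear_bwd(zm4, phi, dwzm, dim(zm4))
  dphi <- weights$alpha * wb$dfield
  dzf <- weights$alpha * array(2 * r / n, d)
  dzm <- weights$alpha * array(wb$dsrc, d)
  l_sm <- smoothness_loss(phi)
  if (weights$beta > 0) dphi <- dphi + weights$beta * smoothness_grad(phi)
  l_aus <- 0
  if (weights$rho > 0 && K >= 1) {
    if (is.null(oh_f)) oh_f <- one_hot(fixed_labels, 1:K)
    if (is.null(oh_m)) oh_m <- one_hot(moving_labels, 1:K)
    woh <- .warp_linear(oh_m, phi, dim(oh_m))
    parts <- soft_dice_parts(oh_f, woh)
    l_aus <- parts$loss
    dwoh <- weights$rho * soft_dice_grad(oh_f, woh, parts)
    wb2 <- .warp_linear_bwd(oh_m, phi, dwoh, dim(oh_m))
    dphi <- dphi + wb2$dfield
  }
  bw <- unet_backward(rnet, fw$cache, dphi, want_input_grad = TRUE)
  dzf <- dzf + bw$dx[, , , 1L]
  dzm <- dzm + bw$dx[, , , 2L]
  list(losses = c(regi = l_regi, smooth = l_sm, aus = l_aus,
                  total = total_registration_loss(
                    c(regi = l_regi, smooth = l_sm, aus = l_aus), weights)),
       dR = bw$dparams, dzf = dzf, dzm = dzm, phi = phi)
}

#' Pre-train the registration network R
#'
#' R consumes the concatenated ground-truth distance representations of each
#' pair and minimizes the total registration loss (similarity + smoothness +
#' auxiliary label overlap).
#'
#' @param pairs List of pairs as produced by [make_pair()].
#' @inheritParams pretrain_feature_net
#' @return An `esdreg_state`.
#' @export
pretrain_reg_net <- function(pairs, cfg = train_config(), net = NULL,
                             use_exponential = TRUE) {
  if (length(pairs) == 0) stop("empty dataset")
  if (is.null(net)) net <- build_reg_net(reg_net_config(seed = cfg$seed + 2L))
  K <- max(pairs[[1]]$fixed_labels)
  zf <- lapply(pairs, function(p)
    rep_from_labels(p$fixed_labels, cfg$gamma, use_exponential))
  zm <- lapply(pairs, function(p)
    rep_from_labels(p$moving_labels, cfg$gamma, use_exponential))
  ohf <- lapply(pairs, function(p) one_hot(p$fixed_labels, 1:K))
  ohm <- lapply(pairs, function(p) one_hot(p$moving_labels, 1:K))
  opt <- adam_init(net$params)
  hist <- list()
  for (ep in seq_len(cfg$epochs)) {
    for (i in epoch_order(length(pairs), cfg$seed + 2L, ep)) {
      ps <- reg_branch_pass(net, zf[[i]], zm[[i]], weights = cfg$weights,
                            K = K, fixed_labels = NULL, moving_labels = NULL,
                            oh_f = ohf[[i]], oh_m = ohm[[i]])
      up <- adam_step(net$params, ps$dR, opt, cfg$learning_rate)
      net$params <- up$params
      opt <- up$state
      hist[[length(hist) + 1L]] <- c(epoch = ep, loss = ps$losses[["total"]])
    }
  }
  new_state(net, opt, "pretrain-R", cfg$epochs, as_history(hist), cfg)
}

# ---- fine-tuning -----------------------------------------------------------

#' Fine-tune the coupled G-R and G-S branches
#'
#' Alternates optimization steps between the registration branch (total
#' registration loss on representations predicted by G) and the segmentation
#' branch (Dice loss on S(G(image))), updating the shared G in both. Each
#' branch has its own Adam optimizer.
#'
#' @param states List with pre-trained `G`, `S`, `R` states (or networks).
#'   All three are required unless `cold_start = TRUE`, which starts from
#'   random initialization (the "without ESDR pre-training" ablation).
#' @param pairs List of pairs from [make_pair()].
#' @param cfg A [train_config()]; `cfg$finetune_alternation` controls how
#'   many steps a branch takes before switching.
#' @param cold_start Allow missing pre-trained networks.
#' @param n_classes Number of segmentation classes (default max label + 1).
#' @return List of `esdreg_state`s `G`, `S`, `R` plus a joint `history`.
#' @export
finetune <- function(states, pairs, cfg = train_config(), cold_start = FALSE,
                     n_classes = NULL) {
  if (length(pairs) == 0) stop("empty dataset")
  K <- max(pairs[[1]]$fixed_labels)
  if (is.null(n_classes)) n_classes <- K + 1
  missing_nets <- vapply(c("G", "S", "R"), function(n) is.null(states[[n]]),
                         logical(1))
  if (any(missing_nets) && !cold_start) {
    stop("fine-tuning requires pre-trained G, S and R states ",
         "(missing: ", paste(c("G", "S", "R")[missing_nets], collapse = ", "),
         "); use cold_start = TRUE for the from-scratch ablation")
  }
  G <- if (is.null(states$G)) {
    build_feature_net(feature_net_config(seed = cfg$seed))
  } else get_net(states$G)
  S <- if (is.null(states$S)) {
    build_seg_net(seg_net_config(n_classes, seed = cfg$seed + 1L))
  } else get_net(states$S)
  R <- if (is.null(states$R)) {
    build_reg_net(reg_net_config(seed = cfg$seed + 2L))
  } else get_net(states$R)
  ohf <- lapply(pairs, function(p) one_hot(p$fixed_labels, 1:K))
  ohm <- lapply(pairs, function(p) one_hot(p$moving_labels, 1:K))
  opt_gr_G <- adam_init(G$params); opt_gr_R <- adam_init(R$params)
  opt_gs_G <- adam_init(G$params); opt_gs_S <- adam_init(S$params)
  hist <- list()
  seg_flip <- 0L
  for (ep in seq_len(cfg$epochs)) {
    for (i in epoch_order(length(pairs), cfg$seed + 3L, ep)) {
      p <- pairs[[i]]
      for (rep_step in seq_len(cfg$finetune_alternation)) {
        # G-R branch step
        fwf <- unet_forward(G, p$fixed, want_cache = TRUE)
        fwm <- unet_forward(G, p$moving, want_cache = TRUE)
        zf <- fwf$out; dim(zf) <- dim(p$fixed)
        zm <- fwm$out; dim(zm) <- dim(p$moving)
        ps <- reg_branch_pass(R, zf, zm, weights = cfg$weights, K = K,
                              fixed_labels = NULL, moving_labels = NULL,
                              oh_f = ohf[[i]], oh_m = ohm[[i]])
        dzf <- ps$dzf; dim(dzf) <- dim(fwf$out)
        dzm <- ps$dzm; dim(dzm) <- dim(fwm$out)
        bwf <- unet_backward(G, fwf$cache, dzf)
        bwm <- unet_backward(G, fwm$cache, dzm)
        dG <- mapply(`+`, bwf$dparams, bwm$dparams, SIMPLIFY = FALSE)
        up <- adam_step(G$params, dG, opt_gr_G, cfg$learning_rate)
        G$params <- up$params; opt_gr_G <- up$state
        up <- adam_step(R$params, ps$dR, opt_gr_R, cfg$learning_rate)
        R$params <- up$params; opt_gr_R <- up$state
        hist[[length(hist) + 1L]] <- c(epoch = ep, branch = 1,
                                       loss = ps$losses[["total"]])
      }
      for (rep_step in seq_len(cfg$finetune_alternation)) {
        # G-S branch step, alternating between the two modalities
        seg_flip <- seg_flip + 1L
        img <- if (seg_flip %% 2L == 1L) p$fixed else p$moving
        lab <- if (seg_flip %% 2L == 1L) p$fixed_labels else p$moving_labels
        fwg <- unet_forward(G, img, want_cache = TRUE)
        fws <- unet_forward(S, fwg$out, want_cache = TRUE)
        gt <- one_hot(lab, 0:(n_classes - 1))
        parts <- soft_dice_parts(gt, fws$out)
        bws <- unet_backward(S, fws$cache,
                              soft_dice_grad(gt, fws$out, parts),
                              want_input_grad = TRUE)
        bwg <- unet_backward(G, fwg$cache, bws$dx)
        up <- adam_step(G$params, bwg$dparams, opt_gs_G, cfg$learning_rate)
        G$params <- up$params; opt_gs_G <- up$state
        up <- adam_step(S$params, bws$dparams, opt_gs_S, cfg$learning_rate)
        S$params <- up$params; opt_gs_S <- up$state
        hist[[length(hist) + 1L]] <- c(epoch = ep, branch = 2,
                                       loss = parts$loss)
      }
    }
  }
  hdf <- as_history(hist)
  list(G = new_state(G, opt_gr_G, "finetune", cfg$epochs, hdf, cfg),
       S = new_state(S, opt_gs_S, "finetune", cfg$epochs, hdf, cfg),
       R = new_state(R, opt_gr_R, "finetune", cfg$epochs, hdf, cfg),
       history = hdf)
}

# ---- inference -------------------------------------------------------------

#' Register a moving image onto a fixed image
#'
#' Both images pass through G; R predicts the displacement field from the
#' concatenated representations; the moving image is warped with trilinear
#' and the optional labels with nearest-neighbour interpolation.
#'
#' @param G,R Trained networks or `esdreg_state`s.
#' @param fixed,moving 3D intensity volumes of matching shape.
#' @param moving_labels Optional 3D label volume to carry along.
#' @return List with `field`, `warped`, `warped_labels` (or `NULL`),
#'   `esdr_fixed`, `esdr_moving`.
#' @export
register_pair <- function(G, R, fixed, moving, moving_labels = NULL) {
  G <- get_net(G); R <- get_net(R)
  if (!all(dim(fixed) == dim(moving))) stop("fixed/moving shapes differ")
  zf <- net_predict(G, fixed)
  zm <- net_predict(G, moving)
  d <- dim(fixed)[1:3]
  xin <- array(0, c(d, 2L))
  xin[, , , 1L] <- zf
  xin[, , , 2L] <- zm
  field <- net_predict(R, xin)
  warped <- warp_linear(moving, field)
  wl <- if (!is.null(moving_labels)) warp_nearest(moving_labels, field)
  list(field = field, warped = warped, warped_labels = wl,
       esdr_fixed = array(zf, d), esdr_moving = array(zm, d))
}

#' Segment a single image
#'
#' @param G,S Trained networks or `esdreg_state`s.
#' @param image 3D intensity volume.
#' @return List with `labels` (argmax, values `0..N-1`) and `probs`
#'   (4D per-class probabilities).
#' @export
segment_image <- function(G, S, image) {
  G <- get_net(G); S <- get_net(S)
  z <- net_predict(G, image)
  probs <- net_predict(S, z)
  d <- dim(probs)
  lab <- max.col(matrix(probs, prod(d[1:3]), d[4]), ties.method = "first") - 1L
  dim(lab) <- d[1:3]
  list(labels = lab, probs = probs)
}
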