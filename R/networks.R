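# U-Net style encoder-decoder networks: the shared feature extractor G,
# the registration network R and the segmentation network S. All three are
# instances of one parametric architecture; forward and backward passes are
# explicit (no external autodiff).

#' Configuration of the feature extraction network G
#'
#' Five resolution stages of two 3x3x3 convolutions each, group
#' normalization and ReLU after every convolution, max-pooling down,
#' transposed-convolution up, skip connections, and a 1x1x1 sigmoid head
#' producing a single-channel distance representation in (0, 1).
#'
#' @param stage_channels Channel width of each of the five stages.
#' @param gn_groups Number of group-normalization groups (capped at the
#'   channel count of a layer).
#' @param seed Integer seed for weight initialization.
#' @return A config list understood by [build_feature_net()].
#' @export
feature_net_config <- function(stage_channels = c(16, 32, 64, 128, 256),
                               gn_groups = 8, seed = 0) {
  stopifnot(length(stage_channels) == 5, all(stage_channels >= 1))
  list(kind = "feature", in_ch = 1L,
       stages = lapply(as.integer(stage_channels), function(c) c(c, c)),
       norm = "gn", act = "relu", gn_groups = as.integer(gn_groups),
       head = list(kernel = 1L, out_ch = 1L, act = "sigmoid",
                   zero_init = FALSE),
       seed = as.integer(seed))
}

#' Configuration of the registration network R
#'
#' Four resolution stages of one 3x3x3 convolution each (16, 32, 32, 32
#' channels), ReLU after every convolution except the last; the head is an
#' unactivated 3x3x3 convolution to 3 displacement channels, zero-initialized
#' so training starts from the identity transform.
#'
#' @inheritParams feature_net_config
#' @return A config list understood by [build_reg_net()].
#' @export
reg_net_config <- function(stage_channels = c(16, 32, 32, 32), seed = 0) {
  stopifnot(length(stage_channels) == 4)
  list(kind = "reg", in_ch = 2L,
       stages = lapply(as.integer(stage_channels), function(c) c(c)),
       norm = "none", act = "relu", gn_groups = 8L,
       head = list(kernel = 3L, out_ch = 3L, act = "none", zero_init = TRUE),
       seed = as.integer(seed))
}

#' Configuration of the segmentation network S
#'
#' Four resolution stages of two 3x3x3 convolutions; the first convolution of
#' each stage has 8, 16, 32, 64 channels and the second doubles it. Group
#' normalization and Leaky ReLU after every convolution; a 1x1x1 convolution
#' head estimates per-class scores, turned into probabilities by a channel
#' softmax.
#'
#' @param n_classes Number of output classes N (background included); >= 2.
#' @param stage_channels First-convolution width of each stage.
#' @inheritParams feature_net_config
#' @return A config list understood by [build_seg_net()].
#' @export
seg_net_config <- function(n_classes, stage_channels = c(8, 16, 32, 64),
                           gn_groups = 8, seed = 0) {
  if (n_classes < 2) stop("n_classes must be at least 2")
  stopifnot(length(stage_channels) == 4)
  list(kind = "seg", in_ch = 1L,
       stages = lapply(as.integer(stage_channels), function(c) c(c, 2L * c)),
       norm = "gn", act = "lrelu", gn_groups = as.integer(gn_groups),
       head = list(kernel = 1L, out_ch = as.integer(n_classes),
                   act = "softmax", zero_init = FALSE),
       seed = as.integer(seed))
}

he_init <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dims)
}

# instantiate parameters for a unet config; names are positional so the
# backward pass can accumulate into a flat list
unet_init <- function(cfg) {
  p <- list()
  with_seed(cfg$seed, {
    L <- length(cfg$stages)
    add_conv <- function(tag, ci, co, kernel = 3L, zero = FALSE) {
      if (kernel == 1L) {
        p[[paste0(tag, "_w")]] <<- if (zero) matrix(0, ci, co) else
          matrix(stats::rnorm(ci * co, sd = sqrt(2 / ci)), ci, co)
      } else {
        p[[paste0(tag, "_w")]] <<- if (zero) array(0, c(3, 3, 3, ci, co)) else
          he_init(c(3, 3, 3, ci, co), 27 * ci)
      }
      p[[paste0(tag, "_b")]] <<- numeric(co)
    }
    add_gn <- function(tag, c) {
      p[[paste0(tag, "_g")]] <<- rep(1, c)
      p[[paste0(tag, "_b")]] <<- numeric(c)
    }
    ci <- cfg$in_ch
    for (i in seq_len(L)) {
      for (j in seq_along(cfg$stages[[i]])) {
        co <- cfg$stages[[i]][j]
        add_conv(sprintf("e%d_c%d", i, j), ci, co)
        if (cfg$norm == "gn") add_gn(sprintf("e%d_n%d", i, j), co)
        ci <- co
      }
    }
    for (i in rev(seq_len(L - 1))) {
      sk <- cfg$stages[[i]][length(cfg$stages[[i]])]
      p[[sprintf("d%d_up_w", i)]] <- he_init(c(2, 2, 2, ci, sk), 8 * ci)
      p[[sprintf("d%d_up_b", i)]] <- numeric(sk)
      ci <- 2L * sk
      widths <- rev(cfg$stages[[i]])
      for (j in seq_along(widths)) {
        co <- widths[j]
        add_conv(sprintf("d%d_c%d", i, j), ci, co)
        if (cfg$norm == "gn") add_gn(sprintf("d%d_n%d", i, j), co)
        ci <- co
      }
    }
    add_conv("head", ci, cfg$head$out_ch, kernel = cfg$head$kernel,
             zero = isTRUE(cfg$head$zero_init))
  })
  p
}

#' Build the feature extraction network G
#'
#' @param cfg A [feature_net_config()].
#' @return A network object (list with `cfg` and `params`) whose forward pass
#'   maps a single-channel volume to a predicted ESDR volume in (0, 1).
#' @export
build_feature_net <- function(cfg = feature_net_config()) {
  structure(list(cfg = cfg, params = unet_init(cfg)), class = "esdreg_net")
}

#' Build the registration network R
#'
#' @param cfg A [reg_net_config()].
#' @return A network object mapping a 2-channel volume (concatenated fixed and
#'   moving distance representations) to a 3-channel displacement field.
#' @export
build_reg_net <- function(cfg = reg_net_config()) {
  structure(list(cfg = cfg, params = unet_init(cfg)), class = "esdreg_net")
}

#' Build the segmentation network S
#'
#' @param cfg A [seg_net_config()].
#' @return A network object mapping a distance representation to per-voxel
#'   class probabilities (N channels summing to one).
#' @export
build_seg_net <- function(cfg) {
  structure(list(cfg = cfg, params = unet_init(cfg)), class = "esdreg_net")
}

#' @export
print.esdreg_net <- function(x, ...) {
  cat(sprintf("<esdreg %s network: %d stages, %s parameters>\n",
              x$cfg$kind, length(x$cfg$stages),
              format(net_param_count(x), big.mark = ",")))
  invisible(x)
}

#' Total number of trainable parameters of a network
#' @param net A network built by one of the `build_*_net()` functions.
#' @return Integer parameter count.
#' @export
net_param_count <- function(net) {
  sum(vapply(net$params, length, integer(1)))
}

check_divisible <- function(shape, levels) {
  f <- 2^(levels - 1)
  if (any(shape %% f != 0)) {
    stop(sprintf(
      "input spatial dims (%s) must be divisible by %d for %d resolution stages",
      paste(shape, collapse = "x"), f, levels))
  }
}

# forward pass; when want_cache the returned cache carries everything
# unet_backward needs
unet_forward <- function(net, x, want_cache = FALSE) {
  cfg <- net$cfg
  p <- net$params
  x <- as_tensor4(x)
  if (dim(x)[4] != cfg$in_ch) {
    stop(sprintf("network expects %d input channel(s), got %d",
                 cfg$in_ch, dim(x)[4]))
  }
  check_divisible(dim(x)[1:3], length(cfg$stages))
  L <- length(cfg$stages)
  cache <- list(enc = vector("list", L), pool = vector("list", L - 1),
                dec = vector("list", L - 1), x = x)
  skips <- vector("list", L - 1)
  conv_block <- function(h, tag, j) {
    cw <- p[[sprintf("%s_c%d_w", tag, j)]]
    cb <- p[[sprintf("%s_c%d_b", tag, j)]]
    xin <- h
    h <- nn_conv3_fwd(h, cw, cb)
    gn <- NULL
    pre <- h
    if (cfg$norm == "gn") {
      gn <- nn_gn_fwd(h, p[[sprintf("%s_n%d_g", tag, j)]],
                      p[[sprintf("%s_n%d_b", tag, j)]], cfg$gn_groups)
      h <- gn$out
      pre <- h
      gn$out <- NULL
    }
    out <- nn_act_fwd(h, cfg$act)
    list(out = out,
         cache = if (want_cache) list(xin = xin, gn = gn, pre = pre,
                                      act_out = out))
  }
  h <- x
  for (i in seq_len(L)) {
    blocks <- vector("list", length(cfg$stages[[i]]))
    for (j in seq_along(cfg$stages[[i]])) {
      cb <- conv_block(h, sprintf("e%d", i), j)
      h <- cb$out
      blocks[[j]] <- cb$cache
    }
    if (want_cache) cache$enc[[i]] <- blocks
    if (i < L) {
      skips[[i]] <- h
      pl <- nn_maxpool2_fwd(h)
      h <- pl$out
      if (want_cache) cache$pool[[i]] <- pl[c("idx", "dims")]
    }
  }
  for (i in rev(seq_len(L - 1))) {
    up_in <- h
    h <- nn_deconv2_fwd(h, p[[sprintf("d%d_up_w", i)]],
                        p[[sprintf("d%d_up_b", i)]])
    nch <- dim(h)[4]
    cat_in <- h
    d <- dim(h)
    hcat <- array(0, c(d[1:3], nch + dim(skips[[i]])[4]))
    hcat[, , , seq_len(nch)] <- h
    hcat[, , , nch + seq_len(dim(skips[[i]])[4])] <- skips[[i]]
    h <- hcat
    blocks <- vector("list", length(cfg$stages[[i]]))
    for (j in seq_along(cfg$stages[[i]])) {
      cb <- conv_block(h, sprintf("d%d", i), j)
      h <- cb$out
      blocks[[j]] <- cb$cache
    }
    if (want_cache) {
      cache$dec[[i]] <- list(up_in = up_in, up_nch = nch, blocks = blocks)
    }
  }
  cache$head_in <- if (want_cache) h
  hk <- cfg$head
  out <- if (hk$kernel == 1L) {
    nn_conv1_fwd(h, p$head_w, p$head_b)
  } else {
    nn_conv3_fwd(h, p$head_w, p$head_b)
  }
  out <- switch(hk$act,
    sigmoid = nn_act_fwd(out, "sigmoid"),
    softmax = nn_softmax_fwd(out),
    none = out)
  if (want_cache) {
    cache$head_out <- out
    list(out = out, cache = cache)
  } else {
    list(out = out)
  }
}

# backward pass: dout is the gradient of a scalar loss w.r.t. the network
# output. Returns dparams (named like net$params) and dx.
unet_backward <- function(net, cache, dout, want_input_grad = FALSE) {
  cfg <- net$cfg
  p <- net$params
  g <- new.env(parent = emptyenv())
  L <- length(cfg$stages)
  hk <- cfg$head
  dh <- switch(hk$act,
    sigmoid = dout * cache$head_out * (1 - cache$head_out),
    softmax = nn_softmax_bwd(cache$head_out, dout),
    none = dout)
  hb <- if (hk$kernel == 1L) {
    nn_conv1_bwd(cache$head_in, p$head_w, dh)
  } else {
    nn_conv3_bwd(cache$head_in, p$head_w, dh)
  }
  g$head_w <- hb$dw
  g$head_b <- hb$db
  dh <- hb$dx
  conv_block_bwd <- function(dh, tag, j, cb, want_dx = TRUE) {
    dh <- nn_act_bwd(cb$pre, cb$act_out, cfg$act, dh)
    if (cfg$norm == "gn") {
      gb <- nn_gn_bwd(cb$gn, p[[sprintf("%s_n%d_g", tag, j)]], dh)
      g[[sprintf("%s_n%d_g", tag, j)]] <- gb$dgamma
      g[[sprintf("%s_n%d_b", tag, j)]] <- gb$dbeta
      dh <- gb$dx
    }
    cvb <- nn_conv3_bwd(cb$xin, p[[sprintf("%s_c%d_w", tag, j)]], dh,
                        want_dx = want_dx)
    g[[sprintf("%s_c%d_w", tag, j)]] <- cvb$dw
    g[[sprintf("%s_c%d_b", tag, j)]] <- cvb$db
    cvb$dx
  }
  dskips <- vector("list", L - 1)
  for (i in seq_len(L - 1)) {
    dc <- cache$dec[[i]]
    for (j in rev(seq_along(cfg$stages[[i]]))) {
      dh <- conv_block_bwd(dh, sprintf("d%d", i), j, dc$blocks[[j]])
    }
    nch <- dc$up_nch
    dskips[[i]] <- dh[, , , nch + seq_len(dim(dh)[4] - nch), drop = FALSE]
    dup <- dh[, , , seq_len(nch), drop = FALSE]
    ub <- nn_deconv2_bwd(dc$up_in, p[[sprintf("d%d_up_w", i)]], dup)
    g[[sprintf("d%d_up_w", i)]] <- ub$dw
    g[[sprintf("d%d_up_b", i)]] <- ub$db
    dh <- ub$dx
  }
  for (i in rev(seq_len(L))) {
    if (i < L) {
      dh <- nn_maxpool2_bwd(cache$pool[[i]], dh)
      dh <- dh + dskips[[i]]
    }
    for (j in rev(seq_along(cfg$stages[[i]]))) {
      dh <- conv_block_bwd(dh, sprintf("e%d", i), j, cache$enc[[i]][[j]],
                           want_dx = !(i == 1 && j == 1) || want_input_grad)
    }
  }
  dparams <- as.list(g)[names(p)]
  names(dparams) <- names(p)
  list(dparams = dparams, dx = dh)
}

# convenience: forward without cache, returning the output tensor
net_predict <- function(net, x) unet_forward(net, x, want_cache = FALSE)$out
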