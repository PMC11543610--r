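# Training objectives. All losses reduce to voxel means so they remain on
# compatible scales under unit weights. Forward values are exported; the
# gradients used by the training loops live alongside as internal functions.

DICE_EPS <- 1e-5

#' Loss weights for the registration objective
#'
#' `L_R = alpha * L_regi + beta * L_smooth + rho * L_aus`. All default to 1.
#'
#' @param alpha Weight of the distance-representation similarity term.
#' @param beta Weight of the field smoothness regularizer.
#' @param rho Weight of the auxiliary label-overlap term; 0 gives a fully
#'   unsupervised registration loss.
#' @return A `loss_weights` list.
#' @export
loss_weights <- function(alpha = 1, beta = 1, rho = 1) {
  stopifnot(alpha >= 0, beta >= 0, rho >= 0)
  structure(list(alpha = alpha, beta = beta, rho = rho),
            class = "loss_weights")
}

#' Huber regression loss between predicted and ground-truth representations
#'
#' Per-voxel Huber of `Diff = pred - gt` (quadratic up to `delta`, linear
#' beyond), averaged over voxels.
#'
#' @param pred,gt Arrays of matching shape.
#' @param delta Positive switch point between the quadratic and linear
#'   regimes.
#' @return Scalar loss.
#' @export
huber_regression_loss <- function(pred, gt, delta = 1) {
  if (!all(dim(pred) == dim(gt))) stop("pred and gt shapes differ")
  if (delta <= 0) stop("delta must be positive")
  d <- abs(unclass(pred) - unclass(gt))
  mean(ifelse(d <= delta, 0.5 * d^2, delta * d - 0.5 * delta^2))
}

huber_grad <- function(pred, gt, delta = 1) {
  df <- unclass(pred) - unclass(gt)
  pmin(pmax(df, -delta), delta) / length(df)
}

#' Registration similarity loss
#'
#' Mean squared error between the fixed distance representation and the
#' warped moving one: `mean[(ESDR_f - W(ESDR_m, phi))^2]`.
#'
#' @param esdr_f,esdr_m Fixed and moving representations (same shape).
#' @param field Displacement field applied to `esdr_m`.
#' @return Scalar loss.
#' @export
registration_mse_loss <- function(esdr_f, esdr_m, field) {
  if (!all(dim(esdr_f)[1:3] == dim(esdr_m)[1:3])) stop("shapes differ")
  w <- warp_linear(esdr_m, field)
  mean((unclass(esdr_f) - unclass(w))^2)
}

#' Displacement-field smoothness loss
#'
#' Forward-difference gradients of all three components along all three
#' axes; each of the nine component-axis pairs contributes the mean of its
#' squared differences (the last slice along each axis has no forward
#' neighbour and is omitted).
#'
#' @param field 4D displacement array `(nx, ny, nz, 3)`.
#' @return Scalar loss; 0 for any constant (translation) field.
#' @export
smoothness_loss <- function(field) {
  d <- dim(field)
  if (length(d) != 4 || d[4] != 3) stop("field must be (nx, ny, nz, 3)")
  tot <- 0
  for (a in 1:3) {
    df <- field_diff(field, a)
    tot <- tot + mean(df^2) * 3 # 3 components share one mean; see below
  }
  tot
}

# forward differences of all components along axis a; result keeps the
# component dimension so mean(df^2)*3 equals the sum over components of
# per-component means
field_diff <- function(field, a) {
  d <- dim(field)
  n <- d[a]
  idx <- lapply(d, seq_len)
  hi <- idx; hi[[a]] <- 2:n
  lo <- idx; lo[[a]] <- 1:(n - 1)
  do.call(`[`, c(list(field), hi)) - do.call(`[`, c(list(field), lo))
}

smoothness_grad <- function(field) {
  d <- dim(field)
  g <- array(0, d)
  for (a in 1:3) {
    df <- field_diff(field, a)
    dd <- 2 * df * 3 / length(df)
    idx <- lapply(d, seq_len)
    hi <- idx; hi[[a]] <- 2:d[a]
    lo <- idx; lo[[a]] <- 1:(d[a] - 1)
    gh <- do.call(`[`, c(list(g), hi))
    do.call(`[<-`, c(list(g), hi, list(gh + dd))) -> g
    gl <- do.call(`[`, c(list(g), lo))
    do.call(`[<-`, c(list(g), lo, list(gl - dd))) -> g
  }
  g
}

#' Dice overlap of two (possibly soft) masks
#'
#' `2 |a ∩ b| / (|a| + |b|)` with the intersection as the voxelwise product.
#' Returns 1 when both masks are empty.
#'
#' @param a,b Arrays with values in `[0, 1]` and matching shape.
#' @return Scalar in `[0, 1]`.
#' @export
dice_score <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("mask shapes differ")
  sa <- sum(a); sb <- sum(b)
  if (sa == 0 && sb == 0) return(1)
  2 * sum(a * b) / (sa + sb)
}

one_hot <- function(labels, values) {
  d <- dim(labels)
  out <- array(0, c(d, length(values)))
  for (i in seq_along(values)) out[, , , i] <- (labels == values[i]) * 1.0
  out
}

#' Auxiliary label-overlap loss for registration
#'
#' One minus the mean Dice over the K foreground structures between the
#' fixed labels and the warped moving labels. During training the one-hot
#' moving channels are warped with trilinear interpolation so the loss is
#' differentiable in the field; use [dsc_percent()] with [warp_nearest()]
#' for evaluation.
#'
#' @param fixed_labels,moving_labels 3D label arrays sharing the value set
#'   `{0..K}`.
#' @param field Displacement field applied to the moving labels.
#' @param K Number of foreground structures (>= 1).
#' @return Scalar loss in `[0, 1]`.
#' @export
auxiliary_dice_loss <- function(fixed_labels, moving_labels, field, K) {
  if (K < 1) stop("K must be at least 1")
  soft_dice_parts(one_hot(fixed_labels, 1:K),
                  warp_linear(one_hot(moving_labels, 1:K), field))$loss
}

# soft dice over channels; returns loss and per-channel pieces for gradients
soft_dice_parts <- function(gt, pred) {
  C <- dim(gt)[4]
  num <- den <- dsc <- numeric(C)
  for (c in seq_len(C)) {
    p <- pred[, , , c]; g <- gt[, , , c]
    num[c] <- 2 * sum(p * g)
    den[c] <- sum(p) + sum(g) + DICE_EPS
    dsc[c] <- num[c] / den[c]
  }
  list(loss = 1 - mean(dsc), num = num, den = den, dsc = dsc)
}

# gradient of soft_dice_parts$loss w.r.t. pred
soft_dice_grad <- function(gt, pred, parts) {
  C <- dim(gt)[4]
  dp <- array(0, dim(pred))
  for (c in seq_len(C)) {
    g <- gt[, , , c]
    dp[, , , c] <- -(2 * g * parts$den[c] - parts$num[c]) / parts$den[c]^2 / C
  }
  dp
}

#' Segmentation Dice loss
#'
#' One minus the mean soft Dice between predicted class probability maps and
#' the one-hot ground truth, over all `K + 1` classes (background included so
#' the softmax is well posed).
#'
#' @param pred_probs 4D array of per-class probabilities summing to 1 over
#'   the last dimension.
#' @param gt_labels 3D label array with values in `{0..K}`.
#' @param K Number of foreground classes.
#' @return Scalar loss in `[0, 1]`.
#' @export
segmentation_dice_loss <- function(pred_probs, gt_labels, K) {
  if (dim(pred_probs)[4] != K + 1) {
    stop(sprintf("pred_probs has %d channels but K + 1 = %d classes expected",
                 dim(pred_probs)[4], K + 1))
  }
  soft_dice_parts(one_hot(gt_labels, 0:K), pred_probs)$loss
}

#' Total registration loss
#'
#' `alpha * L_regi + beta * L_smooth + rho * L_aus`.
#'
#' @param parts Named list (or vector) with elements `regi`, `smooth`, `aus`.
#' @param weights A [loss_weights()] object.
#' @return Scalar loss.
#' @export
total_registration_loss <- function(parts, weights = loss_weights()) {
  weights$alpha * parts[["regi"]] + weights$beta * parts[["smooth"]] +
    weights$rho * parts[["aus"]]
}
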