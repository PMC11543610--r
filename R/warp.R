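# Spatial warping by a displacement field phi: the warped value at voxel p is
# the source sampled at p + phi[p] (offsets in voxels along axes 1..3).
# Out-of-grid sample coordinates are clamped to the border.

check_field <- function(vol, field) {
  dv <- dim(vol)[1:3]
  df <- dim(field)
  if (length(df) != 4 || df[4] != 3) {
    stop("field must be a 4D array with 3 components in the last dimension")
  }
  if (!all(dv == df[1:3])) {
    stop(sprintf("field shape (%s) does not match volume shape (%s)",
                 paste(df[1:3], collapse = "x"), paste(dv, collapse = "x")))
  }
}

#' Warp a volume with trilinear interpolation
#'
#' Implements `W(V, phi)[p] = V[p + phi[p]]` with trilinear interpolation at
#' non-integer sample points, border-clamped. The operation is differentiable
#' in both the source volume and the field (gradients are used internally
#' during training).
#'
#' @param volume 3D array (or 4D multi-channel array) of intensities or a
#'   distance representation.
#' @param field 4D displacement array `(nx, ny, nz, 3)`, offsets in voxels.
#' @return Warped volume of the same shape and attributes as the input.
#' @export
warp_linear <- function(volume, field) {
  check_field(volume, field)
  was3 <- length(dim(volume)) == 3
  x <- as_tensor4(unclass(volume))
  out <- .warp_linear(x, field, dim(x))
  if (was3) dim(out) <- dim(out)[1:3]
  if (inherits(volume, "distance_rep")) {
    out <- new_distance_rep(out, attr(volume, "kind"), attr(volume, "gamma"),
                            attr(volume, "spacing"))
  }
  out
}

#' Warp a label volume with nearest-neighbour interpolation
#'
#' Sample coordinates are rounded half away from the grid origin after
#' border clamping, so label warps are bit-reproducible. No new label values
#' can appear.
#'
#' @param labels 3D integer array of region labels.
#' @param field 4D displacement array `(nx, ny, nz, 3)`.
#' @return Warped label volume (same storage mode as the input).
#' @export
warp_nearest <- function(labels, field) {
  check_field(labels, field)
  was_int <- is.integer(labels)
  x <- as_tensor4(labels * 1.0)
  out <- .warp_nearest(x, field, dim(x))
  dim(out) <- dim(labels)
  if (was_int) storage.mode(out) <- "integer"
  out
}

warp_linear_bwd <- function(src, field, dout) {
  src <- as_tensor4(src)
  dout <- as_tensor4(dout)
  .warp_linear_bwd(src, field, dout, dim(src))
}

#' Zero displacement field for a given shape
#' @param shape Integer vector of 3 spatial dims.
#' @return 4D array of zeros `(shape, 3)`.
#' @export
zero_field <- function(shape) array(0, c(shape, 3))
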