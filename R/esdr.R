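# Signed distance representation (SDR) and its exponential transform (ESDR).
#
# For a voxel x inside region r, SDR(x) is the Euclidean distance (in spacing
# units) from x to the nearest boundary voxel of r; boundary voxels carry 0.
# Background (label 0) is a region in its own right. The exponential
# transform ESDR(x) = exp(-gamma * SDR(x)) maps boundaries to 1 and decays
# into region interiors, amplifying gradients at boundaries.

#' Inter-region boundary voxels of a label volume
#'
#' A voxel is a boundary voxel iff at least one of its 6-connected neighbours
#' carries a different label. Voxels on the volume edge are compared only
#' against in-bounds neighbours: the image border itself is not a boundary.
#'
#' @param labels 3D integer array of region labels (0 = background).
#' @return 3D logical array, `TRUE` on boundary voxels.
#' @export
region_boundary <- function(labels) {
  d <- dim(labels)
  if (length(d) != 3) stop("labels must be a 3D array")
  b <- array(FALSE, d)
  n1 <- d[1]; n2 <- d[2]; n3 <- d[3]
  if (n1 > 1) {
    df <- labels[-n1, , , drop = FALSE] != labels[-1, , , drop = FALSE]
    b[-n1, , ] <- b[-n1, , , drop = FALSE] | df
    b[-1, , ] <- b[-1, , , drop = FALSE] | df
  }
  if (n2 > 1) {
    df <- labels[, -n2, , drop = FALSE] != labels[, -1, , drop = FALSE]
    b[, -n2, ] <- b[, -n2, , drop = FALSE] | df
    b[, -1, ] <- b[, -1, , drop = FALSE] | df
  }
  if (n3 > 1) {
    df <- labels[, , -n3, drop = FALSE] != labels[, , -1, drop = FALSE]
    b[, , -n3] <- b[, , -n3, drop = FALSE] | df
    b[, , -1] <- b[, , -1, drop = FALSE] | df
  }
  b
}

new_distance_rep <- function(data, kind, gamma = NULL, spacing = c(1, 1, 1)) {
  structure(data, kind = kind, gamma = gamma, spacing = spacing,
            class = c("distance_rep", "array"))
}

#' Signed distance representation of a label volume
#'
#' Computes, for every voxel, the exact Euclidean distance (honouring
#' anisotropic voxel spacing) to the nearest boundary voxel of the region the
#' voxel resides in. Boundary voxels get 0.
#'
#' @param labels 3D integer array; background 0 is treated as a region.
#' @param spacing Physical size of a voxel along each axis.
#' @return A 3D `distance_rep` array with `kind = "SDR"`; all values >= 0.
#' @export
compute_sdr <- function(labels, spacing = c(1, 1, 1)) {
  d <- dim(labels)
  if (length(d) != 3) stop("labels must be a 3D array")
  stopifnot(length(spacing) == 3, all(spacing > 0))
  vals <- sort(unique(as.vector(labels)))
  if (length(vals) < 2) {
    stop("label volume is uniform: no region boundary exists, SDR undefined")
  }
  b <- region_boundary(labels)
  out <- array(0, d)
  for (r in vals) {
    inr <- labels == r
    sites <- b & inr
    dist <- .edt_from_sites(sites, d, as.numeric(spacing))
    out[inr] <- dist[inr]
  }
  new_distance_rep(out, "SDR", spacing = spacing)
}

#' Exponential transform of an SDR
#'
#' `ESDR = exp(-gamma * SDR)`: 1 exactly on region boundaries, strictly
#' decreasing with distance from them.
#'
#' @param sdr A `distance_rep` with `kind = "SDR"` (or a bare non-negative
#'   array).
#' @param gamma Positive decay rate; larger values concentrate the
#'   representation at boundaries.
#' @return A `distance_rep` with `kind = "ESDR"`, values in (0, 1].
#' @export
compute_esdr <- function(sdr, gamma = 1) {
  if (!is.null(attr(sdr, "kind")) && attr(sdr, "kind") != "SDR") {
    stop("compute_esdr expects an SDR input")
  }
  if (gamma <= 0) stop("gamma must be positive")
  new_distance_rep(exp(-gamma * unclass(sdr)), "ESDR", gamma = gamma,
                   spacing = attr(sdr, "spacing") %||% c(1, 1, 1))
}

#' ESDR directly from labels
#'
#' Composition of [compute_sdr()] and [compute_esdr()]. With
#' `per_region = TRUE` a 4D stack is returned instead, channel r holding
#' `exp(-gamma * d_r)` where `d_r` is the distance of every voxel to the
#' boundary of region r.
#'
#' @inheritParams compute_sdr
#' @inheritParams compute_esdr
#' @param per_region Return one channel per region instead of the default
#'   single-channel representation.
#' @return A `distance_rep` (3D, or 4D when `per_region`).
#' @export
esdr_from_labels <- function(labels, gamma = 1, spacing = c(1, 1, 1),
                             per_region = FALSE) {
  if (!per_region) {
    return(compute_esdr(compute_sdr(labels, spacing), gamma))
  }
  if (gamma <= 0) stop("gamma must be positive")
  d <- dim(labels)
  vals <- sort(unique(as.vector(labels)))
  if (length(vals) < 2) stop("label volume is uniform: SDR undefined")
  b <- region_boundary(labels)
  out <- array(0, c(d, length(vals)))
  for (i in seq_along(vals)) {
    sites <- b & (labels == vals[i])
    out[, , , i] <- exp(-gamma * .edt_from_sites(sites, d, as.numeric(spacing)))
  }
  new_distance_rep(out, "ESDR", gamma = gamma, spacing = spacing)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
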