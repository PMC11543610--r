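# Evaluation: per-structure Dice (%) and deformation-smoothness diagnostics
# from the Jacobian of the deformation map p + phi(p).

#' Per-structure Dice similarity (%) between two label volumes
#'
#' Hard Dice per structure, scaled to percent, plus the mean over the listed
#' structures. A structure absent from both volumes scores 100 by convention
#' and is flagged in the report.
#'
#' @param pred_labels,gt_labels 3D label arrays on a shared vocabulary.
#' @param structures Integer vector of structures to report; defaults to the
#'   foreground labels present in either volume.
#' @return List with `per_structure` (named percents), `mean_dsc`, and
#'   `absent` (structures missing from both volumes).
#' @export
dsc_percent <- function(pred_labels, gt_labels, structures = NULL) {
  if (!all(dim(pred_labels) == dim(gt_labels))) stop("shapes differ")
  if (is.null(structures)) {
    structures <- sort(setdiff(
      union(unique(as.vector(pred_labels)), unique(as.vector(gt_labels))), 0))
  }
  per <- numeric(length(structures))
  absent <- integer(0)
  for (i in seq_along(structures)) {
    s <- structures[i]
    a <- pred_labels == s
    b <- gt_labels == s
    if (!any(a) && !any(b)) absent <- c(absent, s)
    per[i] <- 100 * dice_score(a * 1.0, b * 1.0)
  }
  names(per) <- structures
  list(per_structure = per, mean_dsc = mean(per), absent = absent)
}

#' Jacobian determinant map of a deformation
#'
#' Per-voxel determinant of `I + d(phi)/dp`, the local volume change of the
#' deformation map `p + phi(p)`. Partials use forward differences with the
#' last slice along each axis replicated so the map keeps the input size.
#'
#' @param field 4D displacement array `(nx, ny, nz, 3)`.
#' @return 3D array of determinants (1 everywhere for any constant field).
#' @export
jacobian_determinant_map <- function(field) {
  d <- dim(field)
  if (length(d) != 4 || d[4] != 3) stop("field must be (nx, ny, nz, 3)")
  # J[[a]][[b]] = d phi_a / d x_b, forward difference along axis b
  grad_axis <- function(comp, a) {
    n <- dim(comp)[a]
    idx <- lapply(dim(comp), seq_len)
    hi <- idx; hi[[a]] <- c(2:n, n)
    lo <- idx; lo[[a]] <- c(1:(n - 1), n - 1)
    do.call(`[`, c(list(comp), hi)) - do.call(`[`, c(list(comp), lo))
  }
  J <- vector("list", 3)
  for (a in 1:3) {
    comp <- field[, , , a]
    J[[a]] <- lapply(1:3, function(b) {
      g <- grad_axis(comp, b)
      if (a == b) g + 1 else g
    })
  }
  J[[1]][[1]] * (J[[2]][[2]] * J[[3]][[3]] - J[[2]][[3]] * J[[3]][[2]]) -
    J[[1]][[2]] * (J[[2]][[1]] * J[[3]][[3]] - J[[2]][[3]] * J[[3]][[1]]) +
    J[[1]][[3]] * (J[[2]][[1]] * J[[3]][[2]] - J[[2]][[2]] * J[[3]][[1]])
}

#' Folding fraction of a displacement field (%)
#'
#' Percentage of voxels whose deformation Jacobian determinant is
#' non-positive, i.e. where the map p + phi(p) locally folds over itself.
#'
#' @param field 4D displacement array.
#' @return Percentage in `[0, 100]`.
#' @export
folding_fraction <- function(field) {
  100 * mean(jacobian_determinant_map(field) <= 0)
}

#' Aggregate evaluation reports across cases
#'
#' @param reports List of reports as returned by [dsc_percent()] (optionally
#'   augmented with a `folding_fraction` element).
#' @return List with per-metric `mean`, `sd` (population) and a formatted
#'   `"mean ± sd"` string.
#' @export
aggregate_reports <- function(reports) {
  pull <- function(f) vapply(reports, f, numeric(1))
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  agg <- function(x) {
    list(mean = mean(x), sd = pop_sd(x),
         formatted = sprintf("%.2f ± %.2f", mean(x), pop_sd(x)))
  }
  out <- list(mean_dsc = agg(pull(function(r) r$mean_dsc)))
  if (!is.null(reports[[1]]$folding_fraction)) {
    out$folding_fraction <- agg(pull(function(r) r$folding_fraction))
  }
  out
}
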