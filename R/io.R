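# Volume and field I/O (NIfTI via RNifti, multi-page TIFF via the tiff
# package), YAML configuration, checkpoints and JSONL run logs.
#
# Axis convention: arrays are indexed (x, y, z) matching NIfTI's first three
# axes; displacement components live in the 4th dimension of a 4D NIfTI.

volume_format <- function(path) {
  lp <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lp)) return("nifti")
  if (grepl("\\.tiff?$", lp)) return("tiff")
  stop("unknown volume extension: ", basename(path),
       " (expected .nii[.gz] or .tif[f])")
}

#' Read a 3D volume from NIfTI or multi-page TIFF
#'
#' @param path File path; format chosen by extension.
#' @param type `"image"` (float intensities), `"label"` (integers), or
#'   `"auto"` (label iff the payload is integer-valued).
#' @param normalize Min-max rescale intensities to `[0, 1]` (images only).
#' @return 3D array with a `spacing` attribute (voxel size; `(1,1,1)` for
#'   TIFF).
#' @export
read_volume <- function(path, type = c("auto", "image", "label"),
                        normalize = TRUE) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("file not found: ", path)
  fmt <- volume_format(path)
  if (fmt == "nifti") {
    img <- RNifti::readNifti(path)
    spacing <- RNifti::pixdim(img)
    arr <- as.array(img)
  } else {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("reading TIFF requires the 'tiff' package")
    }
    sl <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(sl)) sl <- list(sl)
    arr <- simplify2array(sl)
    spacing <- c(1, 1, 1)
  }
  if (length(dim(arr)) != 3) {
    stop(sprintf("expected a 3D payload, got %dD in %s",
                 length(dim(arr)), basename(path)))
  }
  is_int <- all(arr == round(arr))
  if (type == "auto") type <- if (is_int) "label" else "image"
  if (type == "label") {
    storage.mode(arr) <- "integer"
  } else {
    storage.mode(arr) <- "double"
    if (normalize) {
      rng <- range(arr)
      if (rng[2] > rng[1]) arr <- (arr - rng[1]) / (rng[2] - rng[1])
    }
  }
  attr(arr, "spacing") <- spacing[seq_len(3)]
  arr
}

#' Write a 3D volume to NIfTI or multi-page TIFF
#'
#' @param volume 3D array.
#' @param path Output path; format chosen by extension.
#' @param spacing Voxel size written to the NIfTI header (ignored for TIFF).
#' @export
write_volume <- function(volume, path, spacing = attr(volume, "spacing")) {
  if (is.null(spacing)) spacing <- c(1, 1, 1)
  fmt <- volume_format(path)
  arr <- unclass(volume)
  attributes(arr) <- list(dim = dim(arr))
  if (fmt == "nifti") {
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- spacing
    RNifti::writeNifti(img, path)
  } else {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("writing TIFF requires the 'tiff' package")
    }
    sl <- lapply(seq_len(dim(arr)[3]), function(k) arr[, , k])
    tiff::writeTIFF(sl, path, bits.per.sample = 32L)
  }
  invisible(path)
}

#' Write a displacement field as a 4D NIfTI
#'
#' Components are stored in the 4th dimension in axis order (x, y, z);
#' [read_field()] inverts the operation exactly.
#'
#' @param field 4D array `(nx, ny, nz, 3)`.
#' @param path Output `.nii`/`.nii.gz` path.
#' @export
write_field <- function(field, path) {
  d <- dim(field)
  if (length(d) != 4 || d[4] != 3) stop("field must be (nx, ny, nz, 3)")
  RNifti::writeNifti(RNifti::asNifti(field), path)
  invisible(path)
}

#' Read a displacement field written by [write_field()]
#' @param path A 4D NIfTI path.
#' @return 4D array `(nx, ny, nz, 3)`.
#' @export
read_field <- function(path) {
  arr <- as.array(RNifti::readNifti(path))
  d <- dim(arr)
  if (length(d) != 4 || d[4] != 3) {
    stop("not a displacement field: expected 4D NIfTI with 3 components")
  }
  attributes(arr) <- list(dim = d)
  arr
}

#' Save a training state (config + weights + epoch + seed) to one file
#' @param state An `esdreg_state` (or list of them).
#' @param path Destination `.rds` path.
#' @export
save_checkpoint <- function(state, path) {
  saveRDS(state, path)
  invisible(path)
}

#' Load a checkpoint written by [save_checkpoint()]
#' @param path Checkpoint path.
#' @return The stored state.
#' @export
load_checkpoint <- function(path) readRDS(path)

#' Load a training configuration from YAML
#'
#' Missing keys fall back to [train_config()] defaults (learning rate 1e-3,
#' batch 1, gamma 1, delta 1, unit loss weights); unknown keys are an error.
#'
#' @param path YAML file path; an empty file yields all defaults.
#' @return A `train_config`.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  base <- train_config()
  wkeys <- c("alpha", "beta", "rho")
  known <- setdiff(names(unclass(base)), "weights")
  unknown <- setdiff(names(raw), c(known, "weights"))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  if (!is.null(raw$weights)) {
    wun <- setdiff(names(raw$weights), wkeys)
    if (length(wun)) stop("unknown weights key(s): ", paste(wun, collapse = ", "))
    w <- utils::modifyList(unclass(loss_weights()), raw$weights)
    raw$weights <- do.call(loss_weights, w)
  }
  cfg <- utils::modifyList(unclass(base), raw)
  train_config(learning_rate = cfg$learning_rate, epochs = cfg$epochs,
               weights = if (inherits(cfg$weights, "loss_weights"))
                 cfg$weights else do.call(loss_weights, cfg$weights),
               gamma = cfg$gamma, delta = cfg$delta, seed = cfg$seed,
               finetune_alternation = cfg$finetune_alternation)
}

#' Write a resolved configuration back to YAML
#' @param cfg A `train_config`.
#' @param path Destination path.
#' @export
write_config <- function(cfg, path) {
  x <- unclass(cfg)
  x$weights <- unclass(x$weights)
  attr(x$weights, "class") <- NULL
  yaml::write_yaml(x, path)
  invisible(path)
}

# append one record to a JSONL run log
log_jsonl <- function(record, path) {
  cat(jsonlite::toJSON(record, auto_unbox = TRUE, digits = NA), "\n",
      sep = "", file = path, append = TRUE)
  invisible(path)
}
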