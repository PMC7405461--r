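#' 3D magnitude image volumes
#'
#' A `volume` is the package's universal currency: a 3D array of
#' non-negative, finite magnitude intensities together with its voxel
#' spacing in millimetres and a flag recording whether the intensities
#' have been min-max normalized to `[0, 1]`.
#'
#' @param data Numeric 3D array of finite, non-negative intensities.
#' @param spacing Numeric length-3 voxel spacing in mm (x, y, z).
#' @param normalized Logical; `TRUE` when intensities are known to lie in
#'   `[0, 1]` after min-max normalization.
#' @return An object of class `volume`.
#' @examples
#' v <- as_volume(array(runif(8^3), c(8, 8, 8)), spacing = c(1.6, 1.6, 1.6))
#' dim(v)
#' @export
as_volume <- function(data, spacing = c(1, 1, 1), normalized = FALSE) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    abort("`data` must be a 3D array.")
  }
  storage.mode(data) <- "double"
  if (!all(is.finite(data))) abort("volume intensities must all be finite.")
  if (any(data < 0)) abort("volume intensities must be non-negative (magnitude images).")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    abort("`spacing` must be three positive voxel sizes in mm.")
  }
  if (isTRUE(normalized) && (min(data) < 0 || max(data) > 1)) {
    abort("`normalized = TRUE` requires intensities in [0, 1].")
  }
  structure(list(data = data, spacing = spacing, normalized = isTRUE(normalized)),
            class = "volume")
}

#' @export
dim.volume <- function(x) dim(x$data)

#' @export
print.volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm%s\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              if (x$normalized) ", normalized [0,1]" else ""))
  cat(sprintf("  intensity range [%.4g, %.4g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' @rdname as_volume
#' @param x Object to test.
#' @export
is_volume <- function(x) inherits(x, "volume")

as_volume_like <- function(data, template, normalized = FALSE) {
  as_volume(data, spacing = template$spacing, normalized = normalized)
}

#' Min-max normalize a volume to [0, 1]
#'
#' Maps intensities to `(v - min) / (max - min)`. A constant volume cannot
#' be rescaled; it maps to all zeros with a warning.
#'
#' @param vol A [volume][as_volume].
#' @return A normalized `volume` with the same grid and spacing.
#' @export
normalize01 <- function(vol) {
  stopifnot(is_volume(vol))
  rng <- range(vol$data)
  if (rng[2] - rng[1] <= 0) {
    warn("constant volume: normalize01() maps it to all zeros.")
    return(as_volume(array(0, dim(vol$data)), vol$spacing, normalized = TRUE))
  }
  as_volume((vol$data - rng[1]) / (rng[2] - rng[1]), vol$spacing, normalized = TRUE)
}

#' Read and write volumes as NIfTI-1
#'
#' Voxel spacing is carried in the NIfTI header (`pixdim`).
#'
#' @param path File path, conventionally `.nii` or `.nii.gz`.
#' @return `read_volume()` returns a [volume][as_volume]; `write_volume()`
#'   returns `path` invisibly.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) arr <- arr[, , , 1, drop = TRUE]
  sp <- RNifti::pixdim(img)[1:3]
  # drop the NIfTI header attributes; the volume carries spacing itself
  arr <- array(as.numeric(arr), dim(arr))
  as_volume(arr, spacing = sp)
}

#' @rdname read_volume
#' @param vol A [volume][as_volume].
#' @export
write_volume <- function(vol, path) {
  stopifnot(is_volume(vol))
  img <- RNifti::asNifti(vol$data, pixdim = vol$spacing)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Mean absolute and mean squared voxel difference
#'
#' `l1_loss()` is the training objective used for the residual U-Net:
#' the mean absolute voxel-wise difference. `l2_loss()` is the mean
#' squared difference (the alternative objective); it equals [mse()].
#'
#' @param pred,truth Volumes (or bare 3D arrays) of identical shape.
#' @return A non-negative scalar.
#' @export
l1_loss <- function(pred, truth) {
  a <- vol_data(pred); b <- vol_data(truth)
  check_same_shape(a, b)
  mean(abs(a - b))
}

#' @rdname l1_loss
#' @export
l2_loss <- function(pred, truth) {
  a <- vol_data(pred); b <- vol_data(truth)
  check_same_shape(a, b)
  mean((a - b)^2)
}

vol_data <- function(x) {
  if (is_volume(x)) x$data else if (is.array(x)) x else abort("expected a volume or array.")
}

check_same_shape <- function(a, b) {
  if (!identical(dim(a), dim(b))) {
    abort(sprintf("shape mismatch: %s vs %s",
                  paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")))
  }
  invisible(TRUE)
}
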