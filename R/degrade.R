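#' Low-resolution degradation specification
#'
#' Parameterises the Fourier-domain low-resolution simulator: the central
#' fraction of k-space retained along the phase-encode (y) and
#' slice-encode (z) axes, an additional asymmetric partial-Fourier zeroing
#' applied to both of those axes, an optional in-plane crop applied after
#' reconstruction, and an optional matrix standardisation (centered
#' crop/pad) applied before the transform. The frequency-encode (x) axis
#' is never masked.
#'
#' The defaults retain 50% phase and 50% slice resolution with 6/8
#' partial Fourier, the conditions used to manufacture training pairs.
#' `crop_xy` and `standardize_matrix` default to `NULL` (leave the grid
#' alone); clinical-scale work standardises to `c(256, 256, 96)` and
#' crops in-plane to 192.
#'
#' @param phase_fraction Fraction of the phase-encode extent retained, in (0, 1].
#' @param slice_fraction Fraction of the slice-encode extent retained, in (0, 1].
#' @param partial_fourier Partial-Fourier fraction in (0.5, 1], applied in
#'   both phase and slice directions (6/8 = 0.75 by default).
#' @param crop_xy Optional in-plane crop target (single integer), applied
#'   to both x and y after reconstruction.
#' @param standardize_matrix Optional integer triple: centered crop/pad
#'   target applied before the Fourier transform.
#' @param pf_side Which side of the retained band the partial-Fourier
#'   zeroing removes: `"high"` (highest positive frequencies, default) or
#'   `"low"`.
#' @return An object of class `degradation_spec`.
#' @export
degradation_spec <- function(phase_fraction = 0.5, slice_fraction = 0.5,
                             partial_fourier = 0.75, crop_xy = NULL,
                             standardize_matrix = NULL,
                             pf_side = c("high", "low")) {
  pf_side <- match.arg(pf_side)
  stopifnot(phase_fraction > 0, phase_fraction <= 1,
            slice_fraction > 0, slice_fraction <= 1,
            partial_fourier > 0.5, partial_fourier <= 1)
  if (!is.null(crop_xy)) {
    crop_xy <- as.integer(crop_xy)
    stopifnot(length(crop_xy) == 1L, crop_xy >= 1L)
  }
  if (!is.null(standardize_matrix)) {
    standardize_matrix <- as.integer(standardize_matrix)
    stopifnot(length(standardize_matrix) == 3L, all(standardize_matrix >= 1L))
    if (!is.null(crop_xy) && any(crop_xy > standardize_matrix[1:2])) {
      abort("`crop_xy` must not exceed the standardized in-plane matrix.")
    }
  }
  structure(list(phase_fraction = phase_fraction,
                 slice_fraction = slice_fraction,
                 partial_fourier = partial_fourier,
                 crop_xy = crop_xy,
                 standardize_matrix = standardize_matrix,
                 pf_side = pf_side),
            class = "degradation_spec")
}

#' @export
print.degradation_spec <- function(x, ...) {
  cat(sprintf("<degradation_spec> phase %.0f%%, slice %.0f%%, partial Fourier %.3g (%s side)\n",
              100 * x$phase_fraction, 100 * x$slice_fraction, x$partial_fourier, x$pf_side))
  if (!is.null(x$standardize_matrix))
    cat("  standardize:", paste(x$standardize_matrix, collapse = "x"), "\n")
  if (!is.null(x$crop_xy)) cat("  in-plane crop:", x$crop_xy, "\n")
  invisible(x)
}

identity_degradation <- function() {
  degradation_spec(phase_fraction = 1, slice_fraction = 1, partial_fourier = 1)
}

#' Build a 1D k-space retention vector
#'
#' Works in the centered (fftshift-ed) convention with DC at 0-based index
#' `floor(n/2)`. The retained set is the central band of
#' `round(fraction * n)` lines containing DC (one extra line on the
#' negative-frequency side when the count is odd), from which
#' `round((1 - partial_fourier) * fraction * n)` lines are removed at the
#' highest-positive-frequency end of the band (or the lowest, when
#' `pf_side = "low"`). DC is always retained.
#'
#' @param axis_length Even number of samples along the axis.
#' @param resolution_fraction Fraction of the extent retained, in (0, 1].
#' @param partial_fourier Partial-Fourier fraction in (0.5, 1].
#' @param pf_side `"high"` or `"low"`; see [degradation_spec()].
#' @return Logical retention vector of length `axis_length` (TRUE = keep),
#'   in the centered convention.
#' @export
build_kspace_mask <- function(axis_length, resolution_fraction,
                              partial_fourier = 1, pf_side = "high") {
  n <- as.integer(axis_length)
  stopifnot(n >= 2L, n %% 2L == 0L,
            resolution_fraction > 0, resolution_fraction <= 1,
            partial_fourier > 0.5, partial_fourier <= 1)
  k <- round(resolution_fraction * n)
  dc <- n %/% 2L                      # 0-based DC index in the shifted convention
  lo <- dc - as.integer(ceiling(k / 2))
  hi <- lo + k - 1L                   # = dc + floor(k/2) - 1
  keep <- rep(FALSE, n)
  keep[(lo:hi) + 1L] <- TRUE
  nzero <- round((1 - partial_fourier) * resolution_fraction * n)
  if (k - nzero < 4L) abort("resolution too low: fewer than 4 k-space lines retained.")
  if (nzero > 0) {
    if (pf_side == "high") {
      drop <- seq.int(hi, by = -1L, length.out = nzero)
    } else {
      drop <- seq.int(lo, by = 1L, length.out = nzero)
    }
    if (dc %in% drop) abort("partial-Fourier zeroing would remove the DC line.")
    keep[drop + 1L] <- FALSE
  }
  if (sum(keep) < 4L) abort("resolution too low: fewer than 4 k-space lines retained.")
  if (!keep[dc + 1L]) abort("internal error: DC line not retained.")
  keep
}

fftshift_idx <- function(n) c(seq.int(n %/% 2 + 1L, n), seq_len(n %/% 2))
ifftshift_idx <- function(n) {
  h <- n - n %/% 2
  c(seq.int(h + 1L, n), seq_len(h))
}

fftshift3 <- function(x) {
  d <- dim(x)
  x[fftshift_idx(d[1]), fftshift_idx(d[2]), fftshift_idx(d[3]), drop = FALSE]
}

ifftshift3 <- function(x) {
  d <- dim(x)
  x[ifftshift_idx(d[1]), ifftshift_idx(d[2]), ifftshift_idx(d[3]), drop = FALSE]
}

#' Centered crop or zero-pad of a volume
#'
#' Crops centrally where the input exceeds the target and zero-pads
#' symmetrically where it is smaller; any off-by-one surplus goes to the
#' high-index side.
#'
#' @param vol A [volume][as_volume].
#' @param target Integer triple of output dimensions.
#' @return A `volume` of dimension `target` with unchanged spacing.
#' @export
crop_pad_center <- function(vol, target) {
  stopifnot(is_volume(vol))
  target <- as.integer(target)
  stopifnot(length(target) == 3L, all(target >= 1L))
  out <- crop_pad_array(vol$data, target)
  as_volume(out, vol$spacing, normalized = vol$normalized && max(out) <= 1)
}

crop_pad_array <- function(arr, target) {
  d <- dim(arr)
  idx_src <- idx_dst <- vector("list", 3)
  for (a in 1:3) {
    n <- d[a]; m <- target[a]
    if (n >= m) {
      lo <- (n - m) %/% 2            # extra surplus goes high
      idx_src[[a]] <- seq.int(lo + 1L, lo + m)
      idx_dst[[a]] <- seq_len(m)
    } else {
      lo <- (m - n) %/% 2
      idx_src[[a]] <- seq_len(n)
      idx_dst[[a]] <- seq.int(lo + 1L, lo + n)
    }
  }
  out <- array(0, target)
  out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
    arr[idx_src[[1]], idx_src[[2]], idx_src[[3]], drop = FALSE]
  out
}

#' Simulate a low-resolution acquisition of a high-resolution volume
#'
#' The pipeline: optional matrix standardisation (centered crop/pad) →
#' centered 3D Fourier transform → zeroing of the outer phase- and
#' slice-encode k-space per [build_kspace_mask()] (frequency axis fully
#' retained; the zero-filled k-space keeps the grid size) → inverse
#' transform → magnitude → optional in-plane centered crop → min-max
#' normalization to `[0, 1]`.
#'
#' @param vol A [volume][as_volume]; intensities must be finite.
#' @param spec A [degradation_spec()].
#' @return A normalized low-resolution `volume` on the (possibly cropped)
#'   standardized grid.
#' @seealso [degrade_pair()] for producing an aligned low/high pair.
#' @export
apply_degradation <- function(vol, spec) {
  stopifnot(is_volume(vol), inherits(spec, "degradation_spec"))
  x <- vol$data
  if (!all(is.finite(x))) abort("non-finite input values.")
  if (!is.null(spec$standardize_matrix)) x <- crop_pad_array(x, spec$standardize_matrix)
  d <- dim(x)
  if (any(d %% 2L != 0L)) abort("degradation requires even matrix dimensions.")
  K <- fftshift3(fft(x))
  my <- build_kspace_mask(d[2], spec$phase_fraction, spec$partial_fourier, spec$pf_side)
  mz <- build_kspace_mask(d[3], spec$slice_fraction, spec$partial_fourier, spec$pf_side)
  K[, !my, ] <- 0
  K[, , !mz] <- 0
  img <- fft(ifftshift3(K), inverse = TRUE) / length(K)
  out <- Mod(img)
  if (!is.null(spec$crop_xy)) out <- crop_pad_array(out, c(spec$crop_xy, spec$crop_xy, d[3]))
  normalize01(as_volume(out, vol$spacing))
}

#' Produce an aligned low/high-resolution training pair
#'
#' The low-resolution member comes from [apply_degradation()]; the
#' high-resolution partner receives the same standardisation, in-plane
#' crop and (independent) min-max normalization so the pair stays
#' voxel-aligned. Each member is normalized on its own.
#'
#' @inheritParams apply_degradation
#' @return A list with normalized `volume`s `lr` and `hr`.
#' @export
degrade_pair <- function(vol, spec) {
  lr <- apply_degradation(vol, spec)
  x <- vol$data
  if (!is.null(spec$standardize_matrix)) x <- crop_pad_array(x, spec$standardize_matrix)
  if (!is.null(spec$crop_xy)) {
    d <- dim(x)
    x <- crop_pad_array(x, c(spec$crop_xy, spec$crop_xy, d[3]))
  }
  hr <- normalize01(as_volume(x, vol$spacing))
  list(lr = lr, hr = hr)
}

#' Sinc (zero-padded k-space) upsampling onto a finer grid
#'
#' Interpolates a volume onto a finer grid covering the same field of
#' view by zero-padding its centered spectrum, taking the magnitude of
#' the inverse transform, and renormalizing. Band-limited signals are
#' reproduced exactly. This op only upsamples.
#'
#' @param vol A [volume][as_volume].
#' @param target_spacing Numeric length-3 target voxel spacing (mm); must
#'   tile the source field of view to within half a target voxel per axis.
#' @return A normalized `volume` at the target spacing.
#' @export
upsample_to_grid <- function(vol, target_spacing) {
  stopifnot(is_volume(vol))
  target_spacing <- as.numeric(target_spacing)
  stopifnot(length(target_spacing) == 3L, all(target_spacing > 0))
  d <- dim(vol$data)
  fov <- d * vol$spacing
  nt <- as.integer(round(fov / target_spacing))
  if (any(abs(nt * target_spacing - fov) > target_spacing / 2)) {
    abort("`target_spacing` does not tile the field of view consistently.")
  }
  if (any(nt < d)) abort("upsample_to_grid() only upsamples: target grid is smaller than the source.")
  K <- fftshift3(fft(vol$data))
  Kp <- array(0 + 0i, nt)
  lo <- (nt - d) %/% 2
  Kp[lo[1] + seq_len(d[1]), lo[2] + seq_len(d[2]), lo[3] + seq_len(d[3])] <- K
  img <- fft(ifftshift3(Kp), inverse = TRUE) / length(K)  # scale: /prod(d) * prod(nt)/prod(nt)
  out <- Mod(img)
  normalize01(as_volume(out, fov / nt))
}
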