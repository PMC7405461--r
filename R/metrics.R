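#' Mean squared error between two volumes
#'
#' @param a,b Volumes (or 3D arrays) of identical shape, conventionally
#'   normalized to `[0, 1]`.
#' @return Mean squared voxel difference (0 iff identical).
#' @export
mse <- function(a, b) {
  x <- vol_data(a); y <- vol_data(b)
  check_same_shape(x, y)
  mean((x - y)^2)
}

gaussian_kernel1d <- function(sigma, size) {
  h <- (size - 1) / 2
  k <- exp(-((-h:h)^2) / (2 * sigma^2))
  k / sum(k)
}

#' Structural similarity index of two volumes
#'
#' Volumetric SSIM with a separable 3D Gaussian window (sigma 1.5,
#' truncated at 11^3 support by default) and the conventional stability
#' constants. The local SSIM map is averaged over the interior region
#' where the window fits entirely, so boundary voxels do not bias the
#' score. Symmetric in its arguments; equals 1 iff the volumes are
#' identical at the declared data range.
#'
#' @param a,b Volumes (or 3D arrays) of identical shape.
#' @param data_range Intensity range of the data (1 for normalized volumes).
#' @param sigma Gaussian window standard deviation in voxels.
#' @param size Odd window support per axis (voxels).
#' @param K1,K2 Stability constants.
#' @return Scalar SSIM in `[-1, 1]`.
#' @export
ssim <- function(a, b, data_range = 1, sigma = 1.5, size = 11L,
                 K1 = 0.01, K2 = 0.03) {
  x <- vol_data(a); y <- vol_data(b)
  check_same_shape(x, y)
  d <- dim(x)
  if (any(d < size)) abort("volume smaller than the SSIM window.")
  k <- gaussian_kernel1d(sigma, size)
  di <- as.integer(d)
  f <- function(v) sepconv3d(v, di, k)
  mu1 <- f(x); mu2 <- f(y)
  s11 <- f(x * x) - mu1^2
  s22 <- f(y * y) - mu2^2
  s12 <- f(x * y) - mu1 * mu2
  C1 <- (K1 * data_range)^2
  C2 <- (K2 * data_range)^2
  smap <- ((2 * mu1 * mu2 + C1) * (2 * s12 + C2)) /
    ((mu1^2 + mu2^2 + C1) * (s11 + s22 + C2))
  h <- (size - 1L) %/% 2L
  core <- smap[(h + 1):(d[1] - h), (h + 1):(d[2] - h), (h + 1):(d[3] - h)]
  mean(core)
}

# Trilinear interpolation of vol at mm positions (rows of `pts`), in the
# volume-centred coordinate frame used by the phantom geometry.
trilinear_sample <- function(vol, pts) {
  arr <- vol$data; sp <- vol$spacing; d <- dim(arr)
  # continuous 1-based voxel coordinate of position p: p/sp + n/2 + 0.5
  cx <- pts[, 1] / sp[1] + d[1] / 2 + 0.5
  cy <- pts[, 2] / sp[2] + d[2] / 2 + 0.5
  cz <- pts[, 3] / sp[3] + d[3] / 2 + 0.5
  if (any(cx < 1 | cx > d[1] | cy < 1 | cy > d[2] | cz < 1 | cz > d[3])) {
    abort("sample points fall outside the volume.")
  }
  x0 <- pmin(floor(cx), d[1] - 1); y0 <- pmin(floor(cy), d[2] - 1)
  z0 <- pmin(floor(cz), d[3] - 1)
  fx <- cx - x0; fy <- cy - y0; fz <- cz - z0
  v <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) fx else 1 - fx) * (if (dy) fy else 1 - fy) * (if (dz) fz else 1 - fz)
    v <- v + w * arr[cbind(x0 + dx, y0 + dy, z0 + dz)]
  }
  v
}

probe_basis <- function(normal) {
  ref <- if (abs(normal[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- ref - sum(ref * normal) * normal
  u <- u / sqrt(sum(u^2))
  v <- c(normal[2] * u[3] - normal[3] * u[2],
         normal[3] * u[1] - normal[1] * u[3],
         normal[1] * u[2] - normal[2] * u[1])
  list(u = u, v = v)
}

#' Vessel edge sharpness (mm^-1)
#'
#' Casts `n_rays` equally spaced radial rays from the probe centre in the
#' vessel cross-sectional plane, samples each intensity profile by
#' trilinear interpolation at `sample_step`, min-max normalizes the
#' profile, and takes the maximum absolute forward-difference gradient
#' divided by the step. The per-ray values are averaged; flat rays are
#' excluded with a warning (all-flat is an error). Global affine
#' rescaling of the volume leaves the result unchanged.
#'
#' @param vol A [volume][as_volume].
#' @param probe A [vessel_probe()] whose rays fit inside the volume.
#' @return Mean edge sharpness over rays, in mm^-1, with per-ray values
#'   in attribute `"per_ray"`.
#' @export
edge_sharpness <- function(vol, probe) {
  stopifnot(is_volume(vol), inherits(probe, "vessel_probe"))
  basis <- probe_basis(probe$plane_normal)
  t <- seq(0, probe$ray_length, by = probe$sample_step)
  theta <- 2 * pi * (seq_len(probe$n_rays) - 1) / probe$n_rays
  per_ray <- rep(NA_real_, probe$n_rays)
  for (i in seq_len(probe$n_rays)) {
    dir <- cos(theta[i]) * basis$u + sin(theta[i]) * basis$v
    pts <- cbind(probe$center[1] + t * dir[1],
                 probe$center[2] + t * dir[2],
                 probe$center[3] + t * dir[3])
    prof <- trilinear_sample(vol, pts)
    rng <- range(prof)
    if (rng[2] - rng[1] < 1e-12) next
    prof <- (prof - rng[1]) / (rng[2] - rng[1])
    per_ray[i] <- max(abs(diff(prof))) / probe$sample_step
  }
  if (all(is.na(per_ray))) abort("all probe rays are flat; no edge to measure.")
  if (anyNA(per_ray)) {
    warn(sprintf("%d flat ray(s) excluded from edge sharpness.", sum(is.na(per_ray))))
  }
  out <- mean(per_ray, na.rm = TRUE)
  attr(out, "per_ray") <- per_ray
  out
}

mask_mean <- function(vol, mask, what) {
  if (is.null(mask) || !any(mask)) abort(sprintf("%s mask is empty.", what))
  mean(vol$data[mask])
}

#' Estimated signal-to-noise ratio
#'
#' Ratio of the mean blood-pool intensity to the mean lung ("noise")
#' intensity. Invariant to global positive rescaling of the volume.
#'
#' @param vol A [volume][as_volume].
#' @param masks A list with logical arrays `blood`, `myocardium`, `lung`
#'   (as produced by [generate_phantom()]).
#' @return Scalar eSNR.
#' @export
esnr <- function(vol, masks) {
  b <- mask_mean(vol, masks$blood, "blood")
  l <- mask_mean(vol, masks$lung, "lung")
  if (l <= 0) abort("lung mean intensity is zero; eSNR undefined.")
  b / l
}

#' Estimated contrast-to-noise ratio
#'
#' Ratio of the mean blood-pool intensity to the mean myocardial
#' intensity. Invariant to global positive rescaling.
#'
#' @inheritParams esnr
#' @return Scalar eCNR.
#' @export
ecnr <- function(vol, masks) {
  b <- mask_mean(vol, masks$blood, "blood")
  m <- mask_mean(vol, masks$myocardium, "myocardium")
  if (m <= 0) abort("myocardial mean intensity is zero; eCNR undefined.")
  b / m
}

#' FWHM vessel caliper (mm)
#'
#' Automated vessel diameter: along each of two perpendicular diameters
#' in the probe plane, the background-corrected intensity profile is
#' thresholded at half maximum and the crossing positions located by
#' linear sub-sample interpolation; the diameter is the crossing
#' distance, and the mean of the two diameters is returned.
#'
#' The "maximum" references the central lumen (the profile peak within
#' half the expected radius of the centre) rather than the global
#' profile maximum, so Gibbs ringing at a truncation-blurred border does
#' not inflate the half-max threshold and bias the caliper low. The
#' background is the profile minimum.
#'
#' @inheritParams edge_sharpness
#' @return Mean FWHM diameter in mm, with both per-axis diameters in
#'   attribute `"per_axis"`.
#' @export
fwhm_diameter <- function(vol, probe) {
  stopifnot(is_volume(vol), inherits(probe, "vessel_probe"))
  basis <- probe_basis(probe$plane_normal)
  t <- seq(-probe$ray_length, probe$ray_length, by = probe$sample_step)
  dia <- numeric(2)
  dirs <- list(basis$u, basis$v)
  for (k in 1:2) {
    dir <- dirs[[k]]
    pts <- cbind(probe$center[1] + t * dir[1],
                 probe$center[2] + t * dir[2],
                 probe$center[3] + t * dir[3])
    prof <- trilinear_sample(vol, pts)
    bg <- min(prof)
    lumen <- which(abs(t) <= probe$radius_hint / 2)
    pk_i <- lumen[which.max(prof[lumen])]
    pk <- prof[pk_i]
    if (pk - bg < 1e-9) abort("no vessel signal above background at the probe; FWHM undefined.")
    half <- bg + (pk - bg) / 2
    left <- right <- NA_real_
    for (i in seq(pk_i, 2)) {
      if (prof[i - 1] < half && prof[i] >= half) {
        frac <- (half - prof[i - 1]) / (prof[i] - prof[i - 1])
        left <- t[i - 1] + frac * (t[i] - t[i - 1])
        break
      }
    }
    for (i in seq(pk_i, length(t) - 1)) {
      if (prof[i] >= half && prof[i + 1] < half) {
        frac <- (prof[i] - half) / (prof[i] - prof[i + 1])
        right <- t[i] + frac * (t[i + 1] - t[i])
        break
      }
    }
    if (is.na(left) || is.na(right)) abort("no half-maximum crossing found on a caliper axis.")
    dia[k] <- right - left
  }
  out <- mean(dia)
  attr(out, "per_axis") <- dia
  out
}

#' Bland-Altman agreement analysis
#'
#' Bias is the mean of the paired differences (`test - reference`); the
#' limits of agreement are `bias +/- 1.96 * sd` with the sample (n-1)
#' standard deviation.
#'
#' @param reference,test Equal-length numeric vectors of paired
#'   measurements (length >= 2).
#' @return A one-row tibble with `bias`, `sd`, `loa_low`, `loa_high`, `n`.
#' @export
bland_altman <- function(reference, test) {
  if (length(reference) != length(test)) abort("paired lists must have equal length.")
  if (length(reference) < 2L) abort("Bland-Altman needs at least 2 pairs.")
  d <- test - reference
  bias <- mean(d)
  s <- sd(d)
  tibble::tibble(bias = bias, sd = s,
                 loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
                 n = length(d))
}

#' Full quantitative report for one volume
#'
#' Convenience wrapper assembling the per-volume evaluation suite
#' against a reference: MSE, SSIM, and — when masks and probes are
#' supplied — eSNR, eCNR, mean vessel edge sharpness and FWHM diameters.
#'
#' @param vol Volume under evaluation.
#' @param ref Reference (ground-truth) volume.
#' @param masks Optional region masks (see [esnr()]).
#' @param probes Optional list of [vessel_probe()]s.
#' @return A one-row tibble; per-probe sharpness/diameters are list
#'   columns when probes are given.
#' @export
metric_report <- function(vol, ref, masks = NULL, probes = NULL) {
  out <- tibble::tibble(mse = mse(vol, ref), ssim = ssim(vol, ref))
  if (!is.null(masks)) {
    out$esnr <- esnr(vol, masks)
    out$ecnr <- ecnr(vol, masks)
  }
  if (!is.null(probes)) {
    es <- vapply(probes, function(p) as.numeric(edge_sharpness(vol, p)), numeric(1))
    fw <- vapply(probes, function(p) as.numeric(fwhm_diameter(vol, p)), numeric(1))
    out$edge_sharpness <- mean(es)
    out$edge_sharpness_per_probe <- list(es)
    out$fwhm_diameter_per_probe <- list(fw)
  }
  out
}
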