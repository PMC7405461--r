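#' Specification of a synthetic whole-heart phantom
#'
#' Describes a seeded, fully synthetic 3D volume emulating whole-heart
#' bSSFP contrast: a bright blood-pool ellipsoid wrapped in an
#' intermediate-intensity myocardial shell, bright tubular vessels, and a
#' dark noisy lung background. Geometry is given in millimetres in a
#' coordinate frame centred on the volume. Structure borders are rendered
#' with analytic partial-volume occupancy (3x supersampling per axis) so
#' edges are sub-voxel smooth.
#'
#' @param matrix Integer triple of voxel counts; each entry must be even
#'   and at least 16 (centered Fourier conventions).
#' @param spacing Voxel spacing in mm.
#' @param vessels List of vessel descriptions, each a list with elements
#'   `path` (for a straight vessel: 2 rows of endpoint mm coordinates; for
#'   a quadratic vessel: 3 rows of Bezier control points), `diameter` (mm)
#'   and `intensity` in (0, 1].
#' @param blood_pool List with `center` (mm), `semi_axes` (mm) and
#'   `intensity` for the blood-pool ellipsoid.
#' @param myocardium_shell List with `thickness` (mm) and `intensity`;
#'   the shell wraps the blood-pool ellipsoid.
#' @param lung_intensity Background mean intensity in `[0, 1)`.
#' @param noise_sd Additive Gaussian noise sd applied before the
#'   magnitude operation; non-negative.
#' @param bias_field_amplitude Fractional amplitude of a low-order
#'   (linear + quadratic) multiplicative intensity modulation.
#' @param seed Integer seed; the same spec and seed reproduce the phantom
#'   bit-identically.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(matrix = c(48L, 48L, 48L),
                         spacing = c(1.6, 1.6, 1.6),
                         vessels = default_vessels(),
                         blood_pool = list(center = c(-8, 0, 0),
                                           semi_axes = c(16, 13, 11),
                                           intensity = 0.9),
                         myocardium_shell = list(thickness = 5, intensity = 0.5),
                         lung_intensity = 0.1,
                         noise_sd = 0.02,
                         bias_field_amplitude = 0.05,
                         seed = 1L) {
  matrix <- as.integer(matrix)
  stopifnot(length(matrix) == 3L, all(matrix >= 16L), all(matrix %% 2L == 0L),
            length(spacing) == 3L, all(spacing > 0),
            lung_intensity >= 0, lung_intensity < 1,
            noise_sd >= 0, bias_field_amplitude >= 0)
  fov <- matrix * spacing
  for (v in vessels) {
    stopifnot(is.matrix(v$path), ncol(v$path) == 3L, nrow(v$path) %in% c(2L, 3L),
              v$diameter > 0, v$diameter < min(fov),
              v$intensity > 0, v$intensity <= 1)
  }
  stopifnot(blood_pool$intensity > 0, blood_pool$intensity <= 1,
            all(blood_pool$semi_axes > 0),
            myocardium_shell$thickness > 0,
            myocardium_shell$intensity > 0, myocardium_shell$intensity <= 1)
  structure(list(matrix = matrix, spacing = spacing, vessels = vessels,
                 blood_pool = blood_pool, myocardium_shell = myocardium_shell,
                 lung_intensity = lung_intensity, noise_sd = noise_sd,
                 bias_field_amplitude = bias_field_amplitude,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' @rdname phantom_spec
#' @export
default_vessels <- function() {
  list(
    list(path = rbind(c(18, 10, -30), c(18, 10, 30)),
         diameter = 8, intensity = 0.95),
    list(path = rbind(c(20, -16, -30), c(12, -16, 0), c(20, -16, 30)),
         diameter = 6, intensity = 0.9)
  )
}

#' A 60-ray vessel border probe
#'
#' Defines where and how the radial edge-sharpness and FWHM-caliper
#' metrics sample a vessel: rays fan out from `center` in the plane
#' orthogonal to `plane_normal` (the local vessel direction, so the plane
#' is the vessel cross-section).
#'
#' @param center Probe centre in mm (volume-centred coordinates).
#' @param plane_normal Direction of the vessel axis at the probe; the
#'   rays live in the plane orthogonal to it. Normalised internally.
#' @param radius_hint Approximate vessel radius in mm.
#' @param n_rays Number of equally spaced radial rays (>= 4; 60 by default).
#' @param ray_length Ray length in mm; must exceed `radius_hint`.
#' @param sample_step Profile sampling step in mm.
#' @return An object of class `vessel_probe`.
#' @export
vessel_probe <- function(center, plane_normal, radius_hint,
                         n_rays = 60L, ray_length = radius_hint + 6,
                         sample_step = 0.8) {
  plane_normal <- as.numeric(plane_normal)
  nrm <- sqrt(sum(plane_normal^2))
  stopifnot(length(center) == 3L, length(plane_normal) == 3L, nrm > 0,
            radius_hint > 0, n_rays >= 4L, ray_length > radius_hint,
            sample_step > 0)
  structure(list(center = as.numeric(center), plane_normal = plane_normal / nrm,
                 radius_hint = radius_hint, n_rays = as.integer(n_rays),
                 ray_length = ray_length, sample_step = sample_step),
            class = "vessel_probe")
}

# mm coordinates of voxel centres (volume-centred frame)
axis_coords <- function(n, sp) (seq_len(n) - 0.5 - n / 2) * sp

# occupancy (mean over 3x3x3 subsamples) from a supersampled logical array
downsample_occupancy <- function(sub, n) {
  dim(sub) <- c(3L, n[1], 3L, n[2], 3L, n[3])
  sub <- aperm(sub, c(1L, 3L, 5L, 2L, 4L, 6L))
  dim(sub) <- c(27L, prod(n))
  occ <- colMeans(sub)
  dim(occ) <- n
  occ
}

# Partial-volume occupancy of a structure, computed only inside its mm
# bounding box (2 x 3 matrix of lo/hi rows) via 3x supersampling. `test`
# receives full X, Y, Z mm coordinate arrays and returns a logical array.
occupancy_region <- function(n, sp, bbox, test) {
  occ <- array(0, n)
  idx <- lapply(1:3, function(a) {
    centres <- axis_coords(n[a], sp[a])
    which(centres >= bbox[1, a] - sp[a] & centres <= bbox[2, a] + sp[a])
  })
  if (any(lengths(idx) == 0L)) return(occ)
  subn <- lengths(idx)
  ss <- lapply(1:3, function(a) {
    centres <- axis_coords(n[a], sp[a])[idx[[a]]]
    as.vector(t(outer(centres, c(-1, 0, 1) * sp[a] / 3, "+")))
  })
  ns <- 3L * subn
  X <- array(rep(ss[[1]], times = ns[2] * ns[3]), ns)
  Y <- array(rep(rep(ss[[2]], each = ns[1]), times = ns[3]), ns)
  Z <- array(rep(ss[[3]], each = ns[1] * ns[2]), ns)
  occ[idx[[1]], idx[[2]], idx[[3]]] <- downsample_occupancy(test(X, Y, Z), subn)
  occ
}

ellipsoid_inside <- function(X, Y, Z, center, semi) {
  ((X - center[1]) / semi[1])^2 + ((Y - center[2]) / semi[2])^2 +
    ((Z - center[3]) / semi[3])^2 <= 1
}

# squared scaled ellipsoid coordinate at all points of the (xs, ys, zs) grid
ellipsoid_q <- function(xs, ys, zs, center, semi) {
  t1 <- ((xs - center[1]) / semi[1])^2
  t2 <- ((ys - center[2]) / semi[2])^2
  t3 <- ((zs - center[3]) / semi[3])^2
  outer(outer(t1, t2, "+"), t3, "+")
}

# squared distance from every grid point to a polyline (piecewise segments)
polyline_dist2 <- function(X, Y, Z, pts) {
  d2 <- NULL
  for (s in seq_len(nrow(pts) - 1L)) {
    p <- pts[s, ]; q <- pts[s + 1L, ]
    v <- q - p
    vv <- sum(v^2)
    wx <- X - p[1]; wy <- Y - p[2]; wz <- Z - p[3]
    t <- (wx * v[1] + wy * v[2] + wz * v[3]) / vv
    t[t < 0] <- 0; t[t > 1] <- 1
    dd <- (wx - t * v[1])^2 + (wy - t * v[2])^2 + (wz - t * v[3])^2
    d2 <- if (is.null(d2)) dd else pmin(d2, dd)
  }
  d2
}

# control points -> polyline; quadratic paths become a 17-point Bezier chain
vessel_polyline <- function(path) {
  if (nrow(path) == 2L) return(path)
  t <- seq(0, 1, length.out = 17)
  b <- cbind((1 - t)^2, 2 * t * (1 - t), t^2)
  b %*% path
}

vessel_point <- function(path, t) {
  if (nrow(path) == 2L) (1 - t) * path[1, ] + t * path[2, ]
  else (1 - t)^2 * path[1, ] + 2 * t * (1 - t) * path[2, ] + t^2 * path[3, ]
}

vessel_tangent <- function(path, t) {
  d <- if (nrow(path) == 2L) path[2, ] - path[1, ]
  else 2 * (1 - t) * (path[2, ] - path[1, ]) + 2 * t * (path[3, ] - path[2, ])
  d / sqrt(sum(d^2))
}

#' Generate a synthetic whole-heart phantom
#'
#' Renders the structures of a [phantom_spec()] over the lung background
#' (max-blend with analytic partial-volume edges), applies the low-order
#' bias field, adds Gaussian noise, takes the magnitude, and min-max
#' normalizes to `[0, 1]`. Ground-truth region masks (noiseless geometric
#' supports at voxel centres) and one cross-sectional [vessel_probe()]
#' per vessel are returned alongside.
#'
#' @param spec A [phantom_spec()].
#' @return A list of class `phantom` with elements `volume` (a normalized
#'   [volume][as_volume]), `masks` (list of disjoint logical arrays
#'   `blood`, `myocardium`, `lung`), and `probes` (list of
#'   [vessel_probe()]s, one per vessel).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$matrix; sp <- spec$spacing
  xc <- axis_coords(n[1], sp[1])
  yc <- axis_coords(n[2], sp[2])
  zc <- axis_coords(n[3], sp[3])

  bp <- spec$blood_pool; myo <- spec$myocardium_shell
  outer_semi <- bp$semi_axes + myo$thickness

  bbox_shell <- rbind(bp$center - outer_semi, bp$center + outer_semi)
  occ_blood <- occupancy_region(n, sp, rbind(bp$center - bp$semi_axes,
                                             bp$center + bp$semi_axes),
                                function(X, Y, Z)
                                  ellipsoid_inside(X, Y, Z, bp$center, bp$semi_axes))
  occ_shell <- occupancy_region(n, sp, bbox_shell, function(X, Y, Z)
    ellipsoid_inside(X, Y, Z, bp$center, outer_semi) &
      !ellipsoid_inside(X, Y, Z, bp$center, bp$semi_axes))

  occ_vessels <- vector("list", length(spec$vessels))
  for (i in seq_along(spec$vessels)) {
    v <- spec$vessels[[i]]
    pts <- vessel_polyline(v$path)
    r <- v$diameter / 2
    bbox <- rbind(apply(pts, 2, min) - r, apply(pts, 2, max) + r)
    occ_vessels[[i]] <- occupancy_region(n, sp, bbox, function(X, Y, Z)
      polyline_dist2(X, Y, Z, pts) <= r^2)
  }

  lung <- spec$lung_intensity
  vol <- array(lung, n)
  blend <- function(vol, occ, intensity) {
    pmax(vol, occ * intensity + (1 - occ) * lung)
  }
  vol <- blend(vol, occ_shell, myo$intensity)
  vol <- blend(vol, occ_blood, bp$intensity)
  for (i in seq_along(occ_vessels)) {
    vol <- blend(vol, occ_vessels[[i]], spec$vessels[[i]]$intensity)
  }

  # voxel-centre (noiseless) supports for the region masks
  qc_in <- ellipsoid_q(xc, yc, zc, bp$center, bp$semi_axes)
  qc_out <- ellipsoid_q(xc, yc, zc, bp$center, outer_semi)
  Xc <- array(rep(xc, times = n[2] * n[3]), n)
  Yc <- array(rep(rep(yc, each = n[1]), times = n[3]), n)
  Zc <- array(rep(zc, each = n[1] * n[2]), n)
  mask_blood <- qc_in <= 1
  for (i in seq_along(spec$vessels)) {
    v <- spec$vessels[[i]]
    d2c <- polyline_dist2(Xc, Yc, Zc, vessel_polyline(v$path))
    inside <- d2c <= (v$diameter / 2)^2
    if (!any(inside)) abort(sprintf("vessel %d support is empty on this grid.", i))
    mask_blood <- mask_blood | inside
  }
  mask_myo <- (qc_out <= 1 & qc_in > 1) & !mask_blood
  mask_lung <- !(mask_blood | mask_myo)
  if (!any(qc_in <= 1)) abort("blood_pool support is empty on this grid.")
  if (!any(mask_myo)) abort("myocardium_shell support is empty on this grid.")
  if (!any(mask_lung)) abort("lung background support is empty on this grid.")

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(spec$seed)

  if (spec$bias_field_amplitude > 0) {
    cf <- runif(6, -1, 1)
    xn <- 2 * xc / (n[1] * sp[1]); yn <- 2 * yc / (n[2] * sp[2]); zn <- 2 * zc / (n[3] * sp[3])
    g <- outer(outer(cf[1] * xn + cf[4] * xn^2, cf[2] * yn + cf[5] * yn^2, "+"),
               cf[3] * zn + cf[6] * zn^2, "+")
    g <- g / max(abs(g))
    vol <- vol * (1 + spec$bias_field_amplitude * g)
  }
  if (spec$noise_sd > 0) {
    vol <- vol + array(rnorm(prod(n), sd = spec$noise_sd), n)
  }
  vol <- abs(vol)
  volume <- normalize01(as_volume(vol, sp))

  probes <- lapply(spec$vessels, function(v) {
    vessel_probe(center = vessel_point(v$path, 0.5),
                 plane_normal = vessel_tangent(v$path, 0.5),
                 radius_hint = v$diameter / 2,
                 sample_step = min(sp) / 2)
  })

  structure(list(volume = volume,
                 masks = list(blood = mask_blood, myocardium = mask_myo, lung = mask_lung),
                 probes = probes,
                 spec = spec),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  d <- dim(x$volume$data)
  cat(sprintf("<phantom> %d x %d x %d voxels, %d vessel probe(s), seed %d\n",
              d[1], d[2], d[3], length(x$probes), x$spec$seed))
  invisible(x)
}

#' Build a paired low/high-resolution phantom dataset
#'
#' Generates `n` independent phantoms from a template spec (per-item seeds
#' derived deterministically from `seed`), degrades each with the degrade
#' module, and collects aligned pairs. The result is re-creatable
#' bit-identically from `(spec_template, n, seed, degradation)`.
#'
#' @param spec_template A [phantom_spec()]; its `seed` field is ignored in
#'   favour of per-item derived seeds.
#' @param n Number of pairs (>= 1).
#' @param seed Master integer seed.
#' @param degradation A [degradation_spec()].
#' @param role Metadata tag (`"train"` or `"test"`) recorded per item and
#'   used to enforce train/test disjointness in [validate()].
#' @return An object of class `sr_dataset`: a list with `pairs` (each a
#'   list `lr`, `hr`, `phantom`, `meta`) plus the generating configuration.
#' @export
make_dataset <- function(spec_template, n, seed, degradation, role = "train") {
  stopifnot(inherits(spec_template, "phantom_spec"), n >= 1,
            inherits(degradation, "degradation_spec"))
  n <- as.integer(n)
  # per-item seeds stay inside 32-bit integer range for any master seed
  seeds <- (as.integer(seed) %% 1000000L) * 1000L + seq_len(n)
  pairs <- lapply(seq_len(n), function(i) {
    sp <- spec_template
    sp$seed <- seeds[i]
    ph <- generate_phantom(sp)
    pair <- degrade_pair(ph$volume, degradation)
    list(lr = pair$lr, hr = pair$hr, phantom = ph,
         meta = list(id = sprintf("%s-%03d", role, i), seed = seeds[i], role = role))
  })
  structure(list(pairs = pairs, template = spec_template, seed = as.integer(seed),
                 degradation = degradation, role = role),
            class = "sr_dataset")
}

#' @export
print.sr_dataset <- function(x, ...) {
  cat(sprintf("<sr_dataset> %d %s pair(s), master seed %d\n",
              length(x$pairs), x$role, x$seed))
  invisible(x)
}

#' @export
length.sr_dataset <- function(x) length(x$pairs)

#' Write or read a paired dataset as a directory archive
#'
#' The archive holds one NIfTI volume per low/high-resolution member
#' (`hr_###.nii.gz`, `lr_###.nii.gz`), integer NIfTI label maps for the
#' region masks (1 = blood, 2 = myocardium, 3 = lung), a JSON sidecar per
#' item with probes and seeds, and a JSON manifest carrying the full
#' generating configuration for provenance.
#'
#' @param dataset An [make_dataset()] result.
#' @param dir Directory path (created if missing).
#' @return `write_dataset()` returns `dir` invisibly; `read_dataset()`
#'   returns the reconstructed `sr_dataset` (without phantom geometry,
#'   which lives in the sidecars).
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "sr_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(dataset$pairs)) {
    p <- dataset$pairs[[i]]
    write_volume(p$hr, file.path(dir, sprintf("hr_%03d.nii.gz", i)))
    write_volume(p$lr, file.path(dir, sprintf("lr_%03d.nii.gz", i)))
    if (!is.null(p$phantom)) {
      m <- p$phantom$masks
      lab <- array(0L, dim(m$blood))
      lab[m$blood] <- 1L; lab[m$myocardium] <- 2L; lab[m$lung] <- 3L
      img <- RNifti::asNifti(lab, pixdim = p$phantom$volume$spacing)
      RNifti::writeNifti(img, file.path(dir, sprintf("masks_%03d.nii.gz", i)))
      side <- list(meta = p$meta,
                   probes = lapply(p$phantom$probes, unclass))
      jsonlite::write_json(side, file.path(dir, sprintf("item_%03d.json", i)),
                           auto_unbox = TRUE, digits = NA)
    }
  }
  manifest <- list(n = length(dataset$pairs), seed = dataset$seed, role = dataset$role,
                   template = serialize_spec(dataset$template),
                   degradation = unclass(dataset$degradation))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

serialize_spec <- function(spec) {
  out <- unclass(spec)
  out$vessels <- lapply(out$vessels, function(v) {
    v$path <- apply(v$path, 1, function(r) as.numeric(r), simplify = FALSE)
    v
  })
  out
}

deserialize_spec <- function(lst) {
  num <- function(x) if (is.null(x)) NULL else as.numeric(unlist(x))
  phantom_spec(
    matrix = num(lst$matrix), spacing = num(lst$spacing),
    vessels = lapply(lst$vessels, function(v) {
      list(path = do.call(rbind, lapply(v$path, function(r) as.numeric(unlist(r)))),
           diameter = as.numeric(v$diameter), intensity = as.numeric(v$intensity))
    }),
    blood_pool = list(center = num(lst$blood_pool$center),
                      semi_axes = num(lst$blood_pool$semi_axes),
                      intensity = as.numeric(lst$blood_pool$intensity)),
    myocardium_shell = list(thickness = as.numeric(lst$myocardium_shell$thickness),
                            intensity = as.numeric(lst$myocardium_shell$intensity)),
    lung_intensity = as.numeric(lst$lung_intensity),
    noise_sd = as.numeric(lst$noise_sd),
    bias_field_amplitude = as.numeric(lst$bias_field_amplitude),
    seed = as.integer(lst$seed))
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = FALSE)
  tpl <- deserialize_spec(man$template)
  pairs <- lapply(seq_len(man$n), function(i) {
    list(lr = read_volume(file.path(dir, sprintf("lr_%03d.nii.gz", i))),
         hr = read_volume(file.path(dir, sprintf("hr_%03d.nii.gz", i))),
         phantom = NULL,
         meta = list(id = sprintf("%s-%03d", man$role, i), role = man$role))
  })
  dg <- man$degradation
  opt <- function(x) if (is.null(x)) NULL else unlist(x)
  deg <- degradation_spec(phase_fraction = dg$phase_fraction,
                          slice_fraction = dg$slice_fraction,
                          partial_fourier = dg$partial_fourier,
                          crop_xy = opt(dg$crop_xy),
                          standardize_matrix = opt(dg$standardize_matrix),
                          pf_side = dg$pf_side)
  structure(list(pairs = pairs, template = tpl, seed = man$seed,
                 degradation = deg, role = man$role),
            class = "sr_dataset")
}
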