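test_that("mse matches brute force and detects identity", {
  v <- random_volume(4, 1)
  expect_equal(mse(v, v), 0)
  a <- as_volume(array(0, c(4, 4, 4)))
  b <- as_volume(array(1, c(4, 4, 4)))
  expect_equal(mse(a, b), 1.0)
  set.seed(33)
  x <- array(runif(4^3), c(4, 4, 4))
  y <- array(runif(4^3), c(4, 4, 4))
  acc <- 0
  for (i in seq_along(x)) acc <- acc + (x[i] - y[i])^2
  expect_equal(mse(as_volume(x), as_volume(y)), acc / length(x), tolerance = 1e-12)
  expect_error(mse(random_volume(4), random_volume(8)), "shape")
})

test_that("ssim is 1 iff identical, symmetric, and bounded", {
  v <- random_volume(16, 2)
  expect_equal(ssim(v, v), 1.0, tolerance = 1e-12)
  for (seed in 1:3) {
    a <- random_volume(16, seed)
    b <- random_volume(16, seed + 100)
    s_ab <- ssim(a, b)
    expect_equal(s_ab, ssim(b, a), tolerance = 1e-12)
    expect_lt(s_ab, 1)
    expect_gt(s_ab, -1)
  }
  expect_error(ssim(random_volume(8), random_volume(8)), "window")
})

test_that("ssim agrees with the brute-force windowed oracle", {
  for (seed in c(1, 5, 9)) {
    a <- random_volume(14, seed)
    set.seed(seed + 50)
    # correlated pair: smooth perturbation of a
    b <- as_volume(pmin(pmax(a$data + 0.1 * array(runif(14^3), c(14, 14, 14)), 0), 1))
    expect_equal(ssim(a, b), ssim_bruteforce(a, b), tolerance = 1e-6)
  }
})

test_that("edge sharpness of an analytic Gaussian-blurred edge matches theory", {
  # radial profile: intensity = pnorm((r0 - r) / sigma) around a cylinder
  # of radius r0; the max gradient of the normalized profile is
  # 1 / (sigma * sqrt(2*pi))
  n <- 64L; sp <- 0.5
  sigma <- 2; r0 <- 8
  cc <- (seq_len(n) - 0.5 - n / 2) * sp
  r2 <- outer(cc^2, cc^2, "+")
  slice <- pnorm((r0 - sqrt(r2)) / sigma)
  vol <- as_volume(array(rep(slice, times = 16), c(n, n, 16L)),
                   spacing = c(sp, sp, 4))
  probe <- vessel_probe(center = c(0, 0, 0), plane_normal = c(0, 0, 1),
                        radius_hint = r0, ray_length = r0 + 6, n_rays = 60,
                        sample_step = 0.1)
  es <- edge_sharpness(vol, probe)
  expect_equal(as.numeric(es), 1 / (sigma * sqrt(2 * pi)), tolerance = 0.05)
  # rotational symmetry: all rays agree
  pr <- attr(es, "per_ray")
  expect_lt(max(pr) - min(pr), 0.02 * mean(pr))
})

test_that("a one-voxel step sampled at 1 mm has sharpness 1", {
  # binary cylinder, no partial volume; the probe centre sits on a voxel
  # centre and the 4 axis-aligned rays sample voxel centres exactly, so
  # the normalized profile steps 1 -> 0 over one 1 mm sample
  n <- 32L
  arr <- array(0, c(n, n, n))
  cc <- seq_len(n) - 0.5 - n / 2
  r2 <- outer((cc - 0.5)^2, (cc - 0.5)^2, "+")
  for (k in seq_len(n)) arr[, , k] <- (r2 <= 6^2) * 1.0
  vol <- as_volume(arr, spacing = c(1, 1, 1))
  probe <- vessel_probe(center = c(0.5, 0.5, 0), plane_normal = c(0, 0, 1),
                        radius_hint = 6, ray_length = 10, n_rays = 4,
                        sample_step = 1)
  es <- edge_sharpness(vol, probe)
  expect_equal(as.numeric(es), 1.0, tolerance = 1e-6)
})

test_that("edge sharpness is invariant to affine intensity rescaling", {
  ph <- generate_phantom(small_phantom_spec(seed = 12))
  p <- ph$probes[[1]]
  base <- as.numeric(edge_sharpness(ph$volume, p))
  rescaled <- as_volume(0.25 + 0.5 * ph$volume$data, ph$volume$spacing)
  expect_equal(as.numeric(edge_sharpness(rescaled, p)), base, tolerance = 1e-10)
})

test_that("flat rays are excluded with a warning; all-flat errors", {
  arr <- array(0.5, c(24, 24, 24))
  vol <- as_volume(arr, spacing = c(1, 1, 1))
  probe <- vessel_probe(center = c(0, 0, 0), plane_normal = c(0, 0, 1),
                        radius_hint = 3, ray_length = 8, n_rays = 8,
                        sample_step = 1)
  expect_error(edge_sharpness(vol, probe), "flat")
})

test_that("eSNR and eCNR are mask-mean ratios, scale-invariant", {
  ph <- generate_phantom(phantom_spec())
  m <- ph$masks
  v <- ph$volume
  expect_equal(esnr(v, m), mean(v$data[m$blood]) / mean(v$data[m$lung]),
               tolerance = 1e-12)
  expect_equal(ecnr(v, m), mean(v$data[m$blood]) / mean(v$data[m$myocardium]),
               tolerance = 1e-12)
  v2 <- as_volume(v$data * 3.7, v$spacing)
  expect_equal(esnr(v2, m), esnr(v, m), tolerance = 1e-12)
  expect_equal(ecnr(v2, m), ecnr(v, m), tolerance = 1e-12)
  # trivial constructed cases
  blood <- array(FALSE, c(4, 4, 4)); blood[1:2, , ] <- TRUE
  lung <- !blood
  vals <- array(0.1, c(4, 4, 4)); vals[blood] <- 1.0
  cv <- as_volume(vals)
  expect_equal(esnr(cv, list(blood = blood, lung = lung)), 10)
  expect_equal(ecnr(cv, list(blood = blood, myocardium = blood)), 1.0)
  expect_error(esnr(cv, list(blood = blood, lung = array(FALSE, c(4, 4, 4)))),
               "empty")
})

test_that("FWHM caliper recovers a known cylinder diameter", {
  ph <- generate_phantom(cylinder_phantom(diameter = 8))
  p <- ph$probes[[1]]
  d <- fwhm_diameter(ph$volume, p)
  expect_equal(as.numeric(d), 8, tolerance = 0.25 / 8)  # half-voxel absolute
  per_axis <- attr(d, "per_axis")
  expect_length(per_axis, 2)
  # degradation must not shrink the measured caliber beyond the
  # caliper's own half-voxel precision
  lr <- apply_degradation(ph$volume, degradation_spec())
  half_voxel <- ph$volume$spacing[1] / 2
  expect_gte(as.numeric(fwhm_diameter(lr, p)), as.numeric(d) - half_voxel)
  # homogeneous region has no half-maximum crossing
  flat <- as_volume(array(0.3, c(32, 32, 32)))
  expect_error(fwhm_diameter(flat, vessel_probe(c(0, 0, 0), c(0, 0, 1),
                                                radius_hint = 4, ray_length = 10,
                                                sample_step = 1)),
               "FWHM|crossing")
})

test_that("Bland-Altman matches the closed formula", {
  expect_error(bland_altman(1:3, 1:2), "equal length")
  expect_error(bland_altman(1, 2), "at least 2")
  ba0 <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ba0$bias, 0)
  expect_equal(ba0$loa_low, 0)
  expect_equal(ba0$loa_high, 0)
  ba1 <- bland_altman(c(1, 2, 3), c(2, 3, 4))
  expect_equal(ba1$bias, 1)
  expect_equal(ba1$sd, 0)
  expect_equal(c(ba1$loa_low, ba1$loa_high), c(1, 1))
  set.seed(44)
  ref <- rnorm(20); tst <- ref + rnorm(20, 0.3, 0.2)
  ba <- bland_altman(ref, tst)
  d <- tst - ref
  m <- sum(d) / 20
  s <- sqrt(sum((d - m)^2) / 19)
  expect_equal(ba$bias, m, tolerance = 1e-12)
  expect_equal(ba$sd, s, tolerance = 1e-12)
  expect_equal(ba$loa_low, m - 1.96 * s, tolerance = 1e-12)
  expect_equal(ba$loa_high, m + 1.96 * s, tolerance = 1e-12)
  expect_lte(ba$loa_low, ba$bias)
  expect_gte(ba$loa_high, ba$bias)
})

test_that("metric_report assembles the full suite", {
  ph <- generate_phantom(phantom_spec())
  lr <- apply_degradation(ph$volume, degradation_spec())
  rep <- metric_report(lr, ph$volume, masks = ph$masks, probes = ph$probes)
  expect_s3_class(rep, "tbl_df")
  expect_true(all(c("mse", "ssim", "esnr", "ecnr", "edge_sharpness") %in% names(rep)))
  expect_gt(rep$mse, 0)
  expect_lt(rep$ssim, 1)
  expect_length(rep$fwhm_diameter_per_probe[[1]], 2)
})
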