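test_that("k-space retention band has the forced counts and contains DC", {
  # full retention
  expect_equal(sum(build_kspace_mask(8, 1, 1)), 8)
  # half retention: central 4 lines including DC (0-based index 4 -> R index 5)
  m <- build_kspace_mask(8, 0.5, 1)
  expect_equal(sum(m), 4)
  expect_equal(which(m), 3:6)
  expect_true(m[5])
  # partial Fourier removes the top of the band: 0.75 * 0.5 * 64 = 24 kept
  m64 <- build_kspace_mask(64, 0.5, 0.75)
  expect_equal(sum(m64), 24)
  dc <- 33L
  expect_true(m64[dc])
  # asymmetry about DC: more retained below DC than above
  expect_gt(sum(m64[1:(dc - 1)]), sum(m64[(dc + 1):64]))
  # pf_side = "low" mirrors the asymmetry
  mlo <- build_kspace_mask(64, 0.5, 0.75, pf_side = "low")
  expect_equal(sum(mlo), 24)
  expect_lt(sum(mlo[1:(dc - 1)]), sum(mlo[(dc + 1):64]))
})

test_that("too-low retention errors", {
  expect_error(build_kspace_mask(16, 0.1, 1), "resolution too low")
})

test_that("crop and pad follow the centered conventions", {
  v <- as_volume(array(seq_len(10 * 10 * 10) / 1000, c(10, 10, 10)))
  # identity
  expect_identical(crop_pad_center(v, c(10, 10, 10))$data, v$data)
  # 10 -> 4 keeps indices 4..7 (surplus goes to the high side)
  cr <- crop_pad_center(v, c(4, 10, 10))
  expect_equal(cr$data[, 1, 1], v$data[4:7, 1, 1])
  # 4 -> 10 pads 3 zeros each side
  v4 <- as_volume(array(1, c(4, 4, 4)))
  pd <- crop_pad_center(v4, c(10, 4, 4))
  expect_equal(pd$data[, 1, 1], c(0, 0, 0, 1, 1, 1, 1, 0, 0, 0))
})

test_that("identity degradation reproduces the normalized input", {
  ph <- generate_phantom(small_phantom_spec(seed = 4))
  id <- degradation_spec(1, 1, 1)
  out <- apply_degradation(ph$volume, id)
  expect_lt(max(abs(out$data - normalize01(ph$volume)$data)), 1e-6)
})

test_that("clinical-scale degradation crops in-plane and stays in [0, 1]", {
  set.seed(7)
  v <- as_volume(array(runif(128 * 128 * 32), c(128, 128, 32)),
                 spacing = c(1.6, 1.6, 1.6))
  spec <- degradation_spec(crop_xy = 96, standardize_matrix = c(128, 128, 32))
  lr <- apply_degradation(v, spec)
  expect_equal(dim(lr$data), c(96L, 96L, 32L))
  expect_gte(min(lr$data), 0)
  expect_lte(max(lr$data), 1)
  # the high-resolution partner gets the same crop and stays aligned
  pair <- degrade_pair(v, spec)
  expect_equal(dim(pair$hr$data), c(96L, 96L, 32L))
  expect_equal(pair$hr$data,
               normalize01(crop_pad_center(v, c(96, 96, 32)))$data)
})

test_that("separable mask application matches sequential 1D masking", {
  set.seed(11)
  x <- array(runif(16^3), c(16, 16, 16))
  v <- as_volume(x)
  spec <- degradation_spec(0.5, 0.75, 0.875)
  lr <- apply_degradation(v, spec)
  # sequential: phase axis only, then slice axis only
  s1 <- degradation_spec(phase_fraction = 0.5, slice_fraction = 1,
                         partial_fourier = 0.875)
  s2 <- degradation_spec(phase_fraction = 1, slice_fraction = 0.75,
                         partial_fourier = 0.875)
  K <- cardiosr:::fftshift3(fft(x))
  my <- build_kspace_mask(16, 0.5, 0.875)
  mz <- build_kspace_mask(16, 0.75, 0.875)
  K1 <- K; K1[, !my, ] <- 0          # phase first
  K2 <- K1; K2[, , !mz] <- 0         # then slice
  seq_img <- Mod(fft(cardiosr:::ifftshift3(K2), inverse = TRUE) / length(K2))
  expect_equal(lr$data, normalize01(as_volume(seq_img))$data, tolerance = 1e-12)
})

test_that("zeroing k-space only removes spectral energy", {
  ph <- generate_phantom(small_phantom_spec(seed = 9))
  x <- normalize01(ph$volume)$data
  for (f in c(0.25, 0.5, 0.75)) {
    spec <- degradation_spec(f, f, 0.75)
    K <- cardiosr:::fftshift3(fft(x))
    my <- build_kspace_mask(dim(x)[2], f, 0.75)
    mz <- build_kspace_mask(dim(x)[3], f, 0.75)
    K[, !my, ] <- 0
    K[, , !mz] <- 0
    expect_lt(sum(Mod(K)^2), sum(Mod(fft(x))^2))
  }
})

test_that("low/high pairs are voxel-aligned (zero-lag cross-correlation)", {
  ph <- generate_phantom(small_phantom_spec(seed = 21))
  pair <- degrade_pair(ph$volume, degradation_spec())
  a <- pair$lr$data - mean(pair$lr$data)
  b <- pair$hr$data - mean(pair$hr$data)
  xc <- Re(fft(fft(a) * Conj(fft(b)), inverse = TRUE))
  peak <- which(xc == max(xc), arr.ind = TRUE)[1, ]
  expect_equal(unname(peak), c(1, 1, 1))  # zero circular lag
})

test_that("sinc upsampling doubles a coarse grid and preserves the FOV", {
  # 24 slices at 3.2 mm -> 48 slices at 1.6 mm
  set.seed(3)
  v <- as_volume(array(runif(16 * 16 * 24), c(16, 16, 24)),
                 spacing = c(1.6, 1.6, 3.2))
  up <- upsample_to_grid(v, c(1.6, 1.6, 1.6))
  expect_equal(dim(up$data), c(16L, 16L, 48L))
  expect_equal(up$spacing, c(1.6, 1.6, 1.6))
  expect_error(upsample_to_grid(v, c(3.2, 3.2, 3.2)), "upsample")
  # identity when the target equals the source spacing
  same <- upsample_to_grid(v, v$spacing)
  expect_lt(max(abs(same$data - normalize01(v)$data)), 1e-6)
})

test_that("sinc upsampling reproduces a band-limited cosine exactly", {
  n <- 24L; sp <- 2
  fov <- n * sp
  cyc <- 3  # cycles across the FOV, well inside the retained band
  coord <- function(m, s) (seq_len(m) - 1) * s
  f3 <- function(x, y, z) {
    0.5 + 0.4 * cos(2 * pi * cyc * x / fov)
  }
  x0 <- coord(n, sp)
  vol <- as_volume(array(f3(rep(x0, times = n * n), 0, 0), c(n, n, n)),
                   spacing = rep(sp, 3))
  up <- upsample_to_grid(vol, rep(1, 3))
  x1 <- coord(2L * n, 1)
  expected <- array(f3(rep(x1, times = (2 * n)^2), 0, 0), rep(2L * n, 3))
  expected <- (expected - min(expected)) / (max(expected) - min(expected))
  expect_lt(max(abs(up$data - expected)), 1e-6)
})
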