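# Shared fixtures and independent oracles for the test suite.

# Small, fast phantom used by unit tests.
small_phantom_spec <- function(seed = 1L, noise_sd = 0.02, bias = 0.05) {
  phantom_spec(matrix = c(32L, 32L, 32L), spacing = c(1.6, 1.6, 1.6),
               vessels = list(list(path = rbind(c(10, 6, -20), c(10, 6, 20)),
                                   diameter = 8, intensity = 0.95)),
               blood_pool = list(center = c(-6, 0, 0), semi_axes = c(11, 9, 8),
                                 intensity = 0.9),
               myocardium_shell = list(thickness = 4, intensity = 0.5),
               noise_sd = noise_sd, bias_field_amplitude = bias, seed = seed)
}

random_volume <- function(n = 16L, seed = 1L, spacing = c(1, 1, 1)) {
  set.seed(seed)
  as_volume(array(runif(n^3), c(n, n, n)), spacing = spacing)
}

# A noiseless cylinder phantom (single bright rod on dark background),
# used by the FWHM caliper and edge-sharpness tests.
cylinder_phantom <- function(diameter = 8, matrix = c(48L, 48L, 48L),
                             spacing = c(0.5, 0.5, 0.5), intensity = 1,
                             background = 0, seed = 1L) {
  phantom_spec(matrix = matrix, spacing = spacing,
               vessels = list(list(
                 path = rbind(c(0, 0, -matrix[3] * spacing[3] / 2),
                              c(0, 0, matrix[3] * spacing[3] / 2)),
                 diameter = diameter, intensity = intensity)),
               blood_pool = list(center = c(matrix[1] * spacing[1] / 4, 0, 0),
                                 semi_axes = rep(spacing[1], 3) * 2.2,
                                 intensity = 0.4),
               myocardium_shell = list(thickness = spacing[1], intensity = 0.2),
               lung_intensity = background, noise_sd = 0,
               bias_field_amplitude = 0, seed = seed)
}

# Brute-force SSIM oracle: per-voxel Gaussian-weighted window statistics
# computed with explicit patch extraction. Independent of the package's
# separable-convolution implementation; O(n^3 * w^3), so keep volumes small.
ssim_bruteforce <- function(a, b, data_range = 1, sigma = 1.5, size = 11L,
                            K1 = 0.01, K2 = 0.03) {
  x <- if (inherits(a, "volume")) a$data else a
  y <- if (inherits(b, "volume")) b$data else b
  d <- dim(x)
  h <- (size - 1L) %/% 2L
  g1 <- exp(-((-h:h)^2) / (2 * sigma^2))
  w <- outer(outer(g1, g1), g1)
  w <- w / sum(w)
  C1 <- (K1 * data_range)^2
  C2 <- (K2 * data_range)^2
  vals <- c()
  for (k in (h + 1):(d[3] - h))
    for (j in (h + 1):(d[2] - h))
      for (i in (h + 1):(d[1] - h)) {
        px <- x[(i - h):(i + h), (j - h):(j + h), (k - h):(k + h)]
        py <- y[(i - h):(i + h), (j - h):(j + h), (k - h):(k + h)]
        mu1 <- sum(w * px); mu2 <- sum(w * py)
        s11 <- sum(w * px * px) - mu1^2
        s22 <- sum(w * py * py) - mu2^2
        s12 <- sum(w * px * py) - mu1 * mu2
        vals <- c(vals, ((2 * mu1 * mu2 + C1) * (2 * s12 + C2)) /
                    ((mu1^2 + mu2^2 + C1) * (s11 + s22 + C2)))
      }
  mean(vals)
}

# Cached desk-scale experiment shared by the acceptance tests: 8 training
# + 4 held-out phantoms at 48^3, two-level network with 8 base channels,
# 30 epochs. Built once per test run on first use.
desk_experiment <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    tpl <- phantom_spec()
    deg <- degradation_spec()
    trainset <- make_dataset(tpl, 8, seed = 101, deg, role = "train")
    testset <- make_dataset(tpl, 4, seed = 202, deg, role = "test")
    fitres <- fit(trainset,
                  network_config(levels = 2, base_channels = 8, seed = 11),
                  train_config(epochs = 30, seed = 12))
    cache <<- list(template = tpl, degradation = deg,
                   trainset = trainset, testset = testset, fit = fitres)
    cache
  }
})
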