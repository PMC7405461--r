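tiny_template <- function() {
  phantom_spec(matrix = c(16, 16, 16), spacing = c(3.2, 3.2, 3.2),
               vessels = list(list(path = rbind(c(8, 8, -25), c(8, 8, 25)),
                                   diameter = 10, intensity = 0.95)),
               blood_pool = list(center = c(-6, -4, 0),
                                 semi_axes = c(12, 10, 9), intensity = 0.9),
               myocardium_shell = list(thickness = 6, intensity = 0.5),
               noise_sd = 0.02, seed = 1)
}

test_that("identity network validation scores super-resolved = low-res", {
  testset <- make_dataset(tiny_template(), 3, seed = 9, degradation_spec(),
                          role = "test")
  net <- build_network(network_config(levels = 2, base_channels = 2, seed = 2))
  net$params$final$W[] <- 0
  net$params$final$b[] <- 0
  val <- validate(net, testset)
  expect_equal(val$per_subject$ssim_sr, val$per_subject$ssim_lr, tolerance = 1e-12)
  expect_equal(val$per_subject$mse_sr, val$per_subject$mse_lr, tolerance = 1e-12)
  expect_equal(val$summary$mean_ssim_delta, 0, tolerance = 1e-12)
  expect_s3_class(tidy(val), "tbl_df")
  expect_equal(glance(val)$n, 3)
})

test_that("validation rejects empty test sets and train/test overlap", {
  net <- build_network(network_config(levels = 2, base_channels = 2, seed = 2))
  empty <- structure(list(pairs = list(), role = "test"), class = "sr_dataset")
  expect_error(validate(net, empty), "empty")
  ds <- make_dataset(tiny_template(), 2, seed = 5, degradation_spec(), role = "train")
  f <- fit(ds, network_config(levels = 2, base_channels = 2, seed = 1),
           train_config(epochs = 1, seed = 1))
  expect_error(validate(f$network, ds), "overlap")
})

test_that("sweep produces one record per admissible fraction", {
  testset <- make_dataset(tiny_template(), 2, seed = 13, degradation_spec(),
                          role = "test")
  net <- build_network(network_config(levels = 2, base_channels = 2, seed = 3))
  fr10 <- seq(0.1, 1, by = 0.1)
  sw <- suppressWarnings(
    generalisability_sweep(net, testset, fr10, degradation_spec()))
  # on a 16-line axis, low fractions fail the >= 4 retained-line rule and
  # are skipped; the remaining fractions each yield one record
  expect_equal(nrow(sw$table) + length(sw$provenance$skipped_fractions), 10)
  expect_true(all(diff(sw$table$fraction) > 0))
  expect_true(all(sw$table$n == 2))
  one <- generalisability_sweep(net, testset, 0.5, degradation_spec())
  expect_equal(nrow(one$table), 1)
})

test_that("sweep at fraction 1 with an identity network gives SSIM 1", {
  testset <- make_dataset(tiny_template(), 2, seed = 17,
                          degradation_spec(1, 1, 1), role = "test")
  net <- build_network(network_config(levels = 2, base_channels = 2, seed = 4))
  net$params$final$W[] <- 0
  net$params$final$b[] <- 0
  sw <- generalisability_sweep(net, testset, 1.0, degradation_spec(1, 1, 1))
  expect_equal(sw$table$mean_ssim, 1, tolerance = 1e-6)
  expect_lt(sw$table$mean_mse, 1e-10)
})

test_that("sweep aggregation equals independent per-subject recomputation", {
  testset <- make_dataset(tiny_template(), 3, seed = 21, degradation_spec(),
                          role = "test")
  net <- build_network(network_config(levels = 2, base_channels = 2, seed = 5))
  f <- 0.5
  sw <- generalisability_sweep(net, testset, f, degradation_spec())
  spec <- degradation_spec(phase_fraction = f, slice_fraction = f)
  per <- vapply(testset$pairs, function(p) {
    pr <- degrade_pair(p$hr, spec)
    sr <- super_resolve(net, pr$lr)
    c(ssim(sr, pr$hr), mse(sr, pr$hr))
  }, numeric(2))
  expect_equal(sw$table$mean_ssim, mean(per[1, ]), tolerance = 1e-12)
  expect_equal(sw$table$sd_ssim, sd(per[1, ]), tolerance = 1e-12)
  expect_equal(sw$table$mean_mse, mean(per[2, ]), tolerance = 1e-12)
})

test_that("end_to_end writes all artifact classes and is re-runnable", {
  dir1 <- file.path(tempdir(), "e2e_a")
  on.exit(unlink(dir1, recursive = TRUE), add = TRUE)
  res <- end_to_end(dir1,
                    template = tiny_template(),
                    net_config = network_config(levels = 2, base_channels = 2, seed = NA),
                    train_cfg = train_config(epochs = 2, seed = NA),
                    n_train = 2, n_test = 2,
                    sweep_fractions = c(0.5, 0.75),
                    master_seed = 5L)
  for (f in c("manifest.json", "run_log.jsonl", "loss_trace.csv",
              "checkpoint.rds", "validation_summary.json", "sweep.csv")) {
    expect_true(file.exists(file.path(dir1, f)), info = f)
  }
  # re-running from the manifest reproduces the validation bit-identically
  dir2 <- file.path(tempdir(), "e2e_b")
  on.exit(unlink(dir2, recursive = TRUE), add = TRUE)
  res2 <- run_from_manifest(res$manifest_path, dir2)
  expect_identical(res$validation$per_subject$ssim_sr,
                   res2$validation$per_subject$ssim_sr)
  expect_identical(res$fit$report$train_loss, res2$fit$report$train_loss)
  expect_identical(res$sweep$table$mean_ssim, res2$sweep$table$mean_ssim)
})

test_that("autoplot methods return ggplot objects", {
  testset <- make_dataset(tiny_template(), 2, seed = 31, degradation_spec(),
                          role = "test")
  net <- build_network(network_config(levels = 2, base_channels = 2, seed = 6))
  sw <- generalisability_sweep(net, testset, c(0.5, 0.75), degradation_spec())
  expect_s3_class(autoplot(sw), "ggplot")
  expect_s3_class(autoplot(sw, metric = "mse"), "ggplot")
  ds <- make_dataset(tiny_template(), 2, seed = 33, degradation_spec())
  fres <- fit(ds, network_config(levels = 2, base_channels = 2, seed = 1),
              train_config(epochs = 1, seed = 1))
  expect_s3_class(autoplot(fres), "ggplot")
})
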