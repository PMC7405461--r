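#' Validate a trained network on a held-out paired dataset
#'
#' Computes per-subject SSIM and MSE for low-resolution-vs-truth and
#' super-resolved-vs-truth, the paired improvement deltas, and cohort
#' mean +/- sd. The test set must be disjoint from the pairs the network
#' was trained on (checked through the dataset metadata tags recorded in
#' the network's provenance).
#'
#' @param net A trained [build_network()]/[fit()] network.
#' @param testset An [make_dataset()] result with role `"test"`.
#' @return An object of class `sr_validation`; [tidy()] returns the
#'   per-subject table, [glance()] the cohort summary.
#' @export
validate <- function(net, testset) {
  stopifnot(inherits(net, "sr_network"), inherits(testset, "sr_dataset"))
  if (length(testset$pairs) == 0L) abort("empty test set.")
  test_ids <- vapply(testset$pairs, function(p) p$meta$id, character(1))
  train_ids <- net$provenance$train_ids
  if (!is.null(train_ids) && length(intersect(train_ids, test_ids)) > 0) {
    abort("test set overlaps the network's training pairs.")
  }
  rows <- purrr::map2_dfr(testset$pairs, test_ids, function(p, id) {
    sr <- super_resolve(net, p$lr)
    tibble::tibble(id = id,
                   ssim_lr = ssim(p$lr, p$hr), ssim_sr = ssim(sr, p$hr),
                   mse_lr = mse(p$lr, p$hr), mse_sr = mse(sr, p$hr))
  })
  rows <- dplyr::mutate(rows,
                        ssim_delta = .data$ssim_sr - .data$ssim_lr,
                        mse_delta = .data$mse_sr - .data$mse_lr)
  summ <- tibble::tibble(
    n = nrow(rows),
    mean_ssim_lr = mean(rows$ssim_lr), sd_ssim_lr = sd(rows$ssim_lr),
    mean_ssim_sr = mean(rows$ssim_sr), sd_ssim_sr = sd(rows$ssim_sr),
    mean_mse_lr = mean(rows$mse_lr), sd_mse_lr = sd(rows$mse_lr),
    mean_mse_sr = mean(rows$mse_sr), sd_mse_sr = sd(rows$mse_sr),
    mean_ssim_delta = mean(rows$ssim_delta),
    mean_mse_delta = mean(rows$mse_delta))
  structure(list(per_subject = rows, summary = summ), class = "sr_validation")
}

#' @export
print.sr_validation <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<sr_validation> n = %d\n", s$n))
  cat(sprintf("  SSIM  low-res %.4f +/- %.4f  ->  super-res %.4f +/- %.4f\n",
              s$mean_ssim_lr, s$sd_ssim_lr, s$mean_ssim_sr, s$sd_ssim_sr))
  cat(sprintf("  MSE   low-res %.3e -> super-res %.3e\n", s$mean_mse_lr, s$mean_mse_sr))
  invisible(x)
}

#' @export
tidy.sr_validation <- function(x, ...) x$per_subject

#' @export
glance.sr_validation <- function(x, ...) x$summary

#' Resolution-generalisability sweep
#'
#' Degrades every high-resolution volume at each retained-resolution
#' fraction (applied to both the phase- and slice-encode axes, partial
#' Fourier held at the template value), super-resolves it, and scores
#' SSIM/MSE against the truth — averaging within each subject's volume
#' first and then across subjects. Fractions whose k-space band would
#' fall below the minimum retained-line rule are skipped with a warning
#' and recorded in the provenance.
#'
#' @param net A trained network.
#' @param highres_set List of high-resolution [volume][as_volume]s (or an
#'   `sr_dataset`, whose `hr` members are used).
#' @param fractions Increasing vector of fractions in (0, 1].
#' @param spec_template A [degradation_spec()] providing the partial
#'   Fourier fraction and crop settings.
#' @return An object of class `sr_sweep` whose `table` is a tibble with
#'   one record per fraction (`fraction`, `mean_ssim`, `sd_ssim`,
#'   `mean_mse`, `sd_mse`, `n`); [tidy()] returns it. [autoplot()] draws
#'   the sweep.
#' @export
generalisability_sweep <- function(net, highres_set, fractions, spec_template) {
  stopifnot(inherits(net, "sr_network"), inherits(spec_template, "degradation_spec"))
  if (inherits(highres_set, "sr_dataset")) {
    highres_set <- lapply(highres_set$pairs, function(p) p$hr)
  }
  stopifnot(length(highres_set) >= 1L, all(fractions > 0), all(fractions <= 1),
            !is.unsorted(fractions, strictly = TRUE))
  skipped <- numeric(0)
  rows <- list()
  for (f in fractions) {
    spec <- spec_template
    spec$phase_fraction <- f
    spec$slice_fraction <- f
    scores <- tryCatch({
      vapply(highres_set, function(hv) {
        pair <- degrade_pair(hv, spec)
        sr <- super_resolve(net, pair$lr)
        c(ssim(sr, pair$hr), mse(sr, pair$hr))
      }, numeric(2))
    }, error = function(e) {
      low <- grepl("resolution too low|remove the DC line", conditionMessage(e))
      if (low) NULL else stop(e)
    })
    if (is.null(scores)) {
      warn(sprintf("fraction %.2f retains too few k-space lines; skipped.", f))
      skipped <- c(skipped, f)
      next
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(
      fraction = f,
      mean_ssim = mean(scores[1, ]), sd_ssim = sd(scores[1, ]),
      mean_mse = mean(scores[2, ]), sd_mse = sd(scores[2, ]),
      n = ncol(scores))
  }
  structure(list(table = dplyr::bind_rows(rows),
                 provenance = list(
                   partial_fourier = spec_template$partial_fourier,
                   trained_fraction = net$provenance$trained_fraction,
                   skipped_fractions = skipped)),
            class = "sr_sweep")
}

#' @export
print.sr_sweep <- function(x, ...) {
  cat("<sr_sweep>\n")
  print(x$table)
  invisible(x)
}

#' @export
tidy.sr_sweep <- function(x, ...) x$table

#' @rdname generalisability_sweep
#' @param object An `sr_sweep`.
#' @param metric `"ssim"` or `"mse"`.
#' @param ... Unused.
#' @export
autoplot.sr_sweep <- function(object, metric = c("ssim", "mse"), ...) {
  metric <- match.arg(metric)
  tb <- object$table
  ycol <- paste0("mean_", metric)
  scol <- paste0("sd_", metric)
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$fraction, y = .data[[ycol]])) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data[[ycol]] - .data[[scol]],
                                      ymax = .data[[ycol]] + .data[[scol]]),
                         alpha = 0.2) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "retained phase/slice resolution fraction",
                  y = paste("mean", toupper(metric), "vs truth")) +
    ggplot2::theme_minimal()
}

#' Run the full seeded pipeline end to end
#'
#' simulate -> degrade -> train -> validate -> sweep as one reproducible
#' pipeline. All randomness flows from `master_seed` through fixed
#' derived substreams (phantoms, weight initialisation, shuffling). The
#' output directory receives the manifest (sufficient to re-run
#' bit-identically), JSON-lines log, checkpoint, per-epoch loss trace,
#' validation tables and sweep table.
#'
#' @param out_dir Artifact directory (created).
#' @param template A [phantom_spec()] template.
#' @param degradation A [degradation_spec()].
#' @param net_config A [network_config()].
#' @param train_cfg A [train_config()].
#' @param n_train,n_test Phantom counts for the two cohorts.
#' @param sweep_fractions Fractions for the generalisability sweep.
#' @param master_seed Master integer seed.
#' @return Invisibly, a list with the trained fit, validation and sweep,
#'   plus `manifest_path`.
#' @export
end_to_end <- function(out_dir,
                       template = phantom_spec(matrix = c(32, 32, 32)),
                       degradation = degradation_spec(),
                       net_config = network_config(levels = 2, base_channels = 4, seed = NA),
                       train_cfg = train_config(epochs = 4, seed = NA),
                       n_train = 4, n_test = 2,
                       sweep_fractions = c(0.3, 0.5, 0.7),
                       master_seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tc_ser <- unclass(train_cfg)
  if (!is.finite(tc_ser$checkpoint_every)) tc_ser$checkpoint_every <- NULL
  if (is.na(tc_ser$seed)) tc_ser$seed <- NULL   # derived from the master seed
  nc_ser <- unclass(net_config)
  if (is.na(nc_ser$seed)) nc_ser$seed <- NULL
  manifest <- list(template = serialize_spec(template),
                   degradation = unclass(degradation),
                   net_config = nc_ser,
                   train_config = tc_ser,
                   n_train = n_train, n_test = n_test,
                   sweep_fractions = sweep_fractions,
                   master_seed = as.integer(master_seed))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  run_stages(manifest, out_dir)
}

#' @rdname end_to_end
#' @param manifest_path Path to a manifest written by a previous run.
#' @export
run_from_manifest <- function(manifest_path, out_dir = dirname(manifest_path)) {
  man <- jsonlite::read_json(manifest_path, simplifyVector = FALSE)
  manifest <- list(template = man$template,
                   degradation = man$degradation,
                   net_config = man$net_config,
                   train_config = man$train_config,
                   n_train = man$n_train, n_test = man$n_test,
                   sweep_fractions = as.numeric(unlist(man$sweep_fractions)),
                   master_seed = as.integer(man$master_seed))
  run_stages(manifest, out_dir)
}

run_stages <- function(manifest, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run_log.jsonl")
  log_stage <- function(stage, ...) {
    rec <- c(list(stage = stage, time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")), list(...))
    cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n", file = log_path, append = TRUE)
  }
  seed <- manifest$master_seed %% 1000000L
  template <- if (inherits(manifest$template, "phantom_spec")) manifest$template
              else deserialize_spec(manifest$template)
  degradation <- as_degradation_spec(manifest$degradation)
  net_config <- as_network_config(manifest$net_config, default_seed = seed * 10L + 2L)
  train_cfg <- as_train_config(manifest$train_config, default_seed = seed * 10L + 3L)

  stage <- "simulate"
  result <- tryCatch({
    log_stage("simulate", seed = seed)
    t0 <- Sys.time()
    trainset <- make_dataset(template, manifest$n_train, seed * 10L, degradation, role = "train")
    testset <- make_dataset(template, manifest$n_test, seed * 10L + 1L, degradation, role = "test")
    log_stage("simulate_done", wall = as.numeric(difftime(Sys.time(), t0, units = "secs")))

    stage <- "train"
    t0 <- Sys.time()
    fit_res <- fit(trainset, net_config, train_cfg)
    utils::write.csv(fit_res$report, file.path(out_dir, "loss_trace.csv"), row.names = FALSE)
    save_network(fit_res$network, file.path(out_dir, "checkpoint.rds"))
    jsonlite::write_json(glance(fit_res), file.path(out_dir, "train_report.json"),
                         auto_unbox = TRUE, digits = NA)
    log_stage("train_done", wall = as.numeric(difftime(Sys.time(), t0, units = "secs")))

    stage <- "validate"
    t0 <- Sys.time()
    val <- validate(fit_res$network, testset)
    utils::write.csv(val$per_subject, file.path(out_dir, "validation_subjects.csv"),
                     row.names = FALSE)
    jsonlite::write_json(val$summary, file.path(out_dir, "validation_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    log_stage("validate_done", wall = as.numeric(difftime(Sys.time(), t0, units = "secs")))

    stage <- "sweep"
    t0 <- Sys.time()
    sweep <- generalisability_sweep(fit_res$network, testset,
                                    manifest$sweep_fractions, degradation)
    utils::write.csv(sweep$table, file.path(out_dir, "sweep.csv"), row.names = FALSE)
    log_stage("sweep_done", wall = as.numeric(difftime(Sys.time(), t0, units = "secs")))

    list(fit = fit_res, validation = val, sweep = sweep,
         manifest_path = file.path(out_dir, "manifest.json"))
  }, error = function(e) {
    log_stage("error", at_stage = stage, message = conditionMessage(e))
    abort(sprintf("pipeline failed at stage '%s': %s", stage, conditionMessage(e)))
  })
  invisible(result)
}

as_degradation_spec <- function(x) {
  if (inherits(x, "degradation_spec")) return(x)
  opt <- function(v) if (is.null(v)) NULL else unlist(v)
  degradation_spec(phase_fraction = x$phase_fraction,
                   slice_fraction = x$slice_fraction,
                   partial_fourier = x$partial_fourier,
                   crop_xy = opt(x$crop_xy),
                   standardize_matrix = opt(x$standardize_matrix),
                   pf_side = if (is.null(x$pf_side)) "high" else x$pf_side)
}

seed_or_default <- function(s, default) {
  s <- suppressWarnings(as.integer(s))
  if (length(s) == 0L || is.na(s)) as.integer(default) else s
}

as_network_config <- function(x, default_seed) {
  if (inherits(x, "network_config")) {
    x$seed <- seed_or_default(x$seed, default_seed)
    return(x)
  }
  seed <- seed_or_default(x$seed, default_seed)
  network_config(levels = x$levels, base_channels = x$base_channels,
                 convs_per_level = x$convs_per_level, residual = x$residual,
                 nonneg_output = x$nonneg_output,
                 upsample = if (is.null(x$upsample)) "nearest_conv" else x$upsample,
                 seed = seed)
}

as_train_config <- function(x, default_seed) {
  if (inherits(x, "train_config")) {
    x$seed <- seed_or_default(x$seed, default_seed)
    return(x)
  }
  seed <- seed_or_default(x$seed, default_seed)
  train_config(epochs = x$epochs, learning_rate = x$learning_rate,
               batch_volumes = x$batch_volumes, loss = x$loss, seed = seed,
               validation_fraction = x$validation_fraction,
               checkpoint_every = if (is.null(x$checkpoint_every)) Inf
                                  else as.numeric(x$checkpoint_every),
               beta1 = x$beta1, beta2 = x$beta2, epsilon = x$epsilon)
}
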