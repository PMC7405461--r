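#' Training recipe configuration
#'
#' The reference recipe minimises the L1 loss between the network output
#' and the ground-truth volume with ADAM (learning rate 1e-3), batching
#' two whole volumes per step, for 200 epochs. Desk-scale runs shrink the
#' epoch count and volume size through this same configuration.
#'
#' @param epochs Number of epochs (>= 1; reference value 200).
#' @param learning_rate ADAM step size (> 0; reference value 1e-3).
#' @param batch_volumes Whole volumes per batch (>= 1; reference value 2).
#' @param loss `"l1"` (mean absolute difference, default) or `"l2"`
#'   (mean squared difference, the comparator objective).
#' @param seed Integer seed driving shuffling.
#' @param validation_fraction Fraction of pairs held out for per-epoch
#'   validation SSIM/MSE (default 0: validate externally).
#' @param checkpoint_every Write a checkpoint every this many epochs when
#'   a checkpoint directory is given to [fit()] (default: final only).
#' @param beta1,beta2,epsilon ADAM moment parameters (conventional
#'   defaults, recorded in the report).
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 200L, learning_rate = 1e-3,
                         batch_volumes = 2L, loss = c("l1", "l2"),
                         seed = 1L, validation_fraction = 0,
                         checkpoint_every = Inf,
                         beta1 = 0.9, beta2 = 0.999, epsilon = 1e-8) {
  loss <- match.arg(loss)
  epochs <- as.integer(epochs); batch_volumes <- as.integer(batch_volumes)
  stopifnot(epochs >= 1L, learning_rate > 0, batch_volumes >= 1L,
            validation_fraction >= 0, validation_fraction < 1)
  structure(list(epochs = epochs, learning_rate = learning_rate,
                 batch_volumes = batch_volumes, loss = loss,
                 seed = as.integer(seed),
                 validation_fraction = validation_fraction,
                 checkpoint_every = checkpoint_every,
                 beta1 = beta1, beta2 = beta2, epsilon = epsilon),
            class = "train_config")
}

loss_value <- function(loss, pred, truth) {
  if (loss == "l1") mean(abs(pred - truth)) else mean((pred - truth)^2)
}

loss_grad <- function(loss, pred, truth) {
  n <- length(pred)
  if (loss == "l1") sign(pred - truth) / n else 2 * (pred - truth) / n
}

#' Train a residual U-Net on paired low/high-resolution volumes
#'
#' Runs the epoch loop with seeded per-epoch shuffling; each step
#' minimises the chosen loss on a batch of whole volumes (no patch
#' extraction), averaging gradients across the batch and applying an
#' ADAM update. The run is fully reproducible from
#' `(dataset, net_config, train_config)` on a fixed platform.
#'
#' @param dataset An [make_dataset()] result (or any list with `pairs`
#'   elements holding `lr`/`hr` volumes of a common shape).
#' @param net_config A [network_config()].
#' @param train_config A [train_config()].
#' @param checkpoint_dir Optional directory for periodic checkpoints.
#' @return An object of class `sr_fit` with elements `network` (the
#'   trained `sr_network`), `report` (per-epoch tibble of training loss
#'   and, when a validation split exists, validation SSIM/MSE) and the
#'   configurations. [tidy()] returns the per-epoch trace; [glance()] a
#'   one-row summary.
#' @export
fit <- function(dataset, net_config, train_config, checkpoint_dir = NULL) {
  stopifnot(inherits(net_config, "network_config"),
            inherits(train_config, "train_config"))
  pairs <- dataset$pairs
  if (length(pairs) == 0L) abort("dataset is empty.")
  shp <- dim(pairs[[1]]$hr$data)
  for (p in pairs) {
    check_same_shape(p$lr$data, p$hr$data)
    check_same_shape(p$hr$data, array(0, shp))
  }
  m <- 2^(net_config$levels - 1L)
  if (any(shp %% m != 0L)) {
    abort(sprintf("volume dims must be divisible by %d for a %d-level network; pad upstream.",
                  m, net_config$levels))
  }

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)

  net <- build_network(net_config)
  tc <- train_config
  set.seed(tc$seed)

  n <- length(pairs)
  n_val <- floor(tc$validation_fraction * n)
  idx <- sample.int(n)
  val_idx <- if (n_val > 0) idx[seq_len(n_val)] else integer(0)
  trn_idx <- setdiff(idx, val_idx)
  if (length(trn_idx) == 0L) abort("validation split leaves no training pairs.")

  state <- list(m = NULL, v = NULL, t = 0L)
  epoch_rows <- vector("list", tc$epochs)
  t0 <- Sys.time()
  ckpts <- character(0)

  for (ep in seq_len(tc$epochs)) {
    order_ep <- trn_idx[sample.int(length(trn_idx))]
    batches <- split(order_ep, ceiling(seq_along(order_ep) / tc$batch_volumes))
    ep_losses <- numeric(0)
    for (bi in seq_along(batches)) {
      b <- batches[[bi]]
      gsum <- NULL
      bloss <- 0
      for (i in b) {
        fw <- network_forward(net, pairs[[i]]$lr$data, keep = TRUE)
        truth <- as_tensor(pairs[[i]]$hr$data)
        lv <- loss_value(tc$loss, fw$out, truth)
        if (!is.finite(lv)) {
          abort(sprintf("non-finite loss at epoch %d, step %d.", ep, bi))
        }
        bloss <- bloss + lv / length(b)
        dout <- loss_grad(tc$loss, fw$out, truth)
        g <- network_backward(net, fw, dout)
        gsum <- if (is.null(gsum)) g else accumulate_grads(gsum, g)
      }
      g <- scale_grads(gsum, 1 / length(b))
      upd <- adam_update(net$params, g, state, tc)
      net$params <- upd$params
      state <- upd$state
      ep_losses <- c(ep_losses, bloss)
    }
    row <- tibble::tibble(epoch = ep, train_loss = mean(ep_losses),
                          val_ssim = NA_real_, val_mse = NA_real_)
    if (length(val_idx) > 0) {
      vs <- vapply(val_idx, function(i) {
        sr <- super_resolve(net, pairs[[i]]$lr)
        c(ssim(sr, pairs[[i]]$hr), mse(sr, pairs[[i]]$hr))
      }, numeric(2))
      row$val_ssim <- mean(vs[1, ]); row$val_mse <- mean(vs[2, ])
    }
    epoch_rows[[ep]] <- row
    if (!is.null(checkpoint_dir) && (ep %% tc$checkpoint_every == 0 || ep == tc$epochs)) {
      dir.create(checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
      ck <- file.path(checkpoint_dir, sprintf("epoch_%04d.rds", ep))
      net$provenance <- fit_provenance(dataset, net_config, tc, trn_idx)
      save_network(net, ck)
      ckpts <- c(ckpts, ck)
    }
  }

  net$provenance <- fit_provenance(dataset, net_config, tc, trn_idx)
  report <- dplyr::bind_rows(epoch_rows)
  structure(list(network = net, report = report,
                 net_config = net_config, train_config = tc,
                 wall_time = as.numeric(difftime(Sys.time(), t0, units = "secs")),
                 checkpoints = ckpts,
                 train_ids = train_pair_ids(pairs, trn_idx),
                 val_ids = train_pair_ids(pairs, val_idx)),
            class = "sr_fit")
}

train_pair_ids <- function(pairs, idx) {
  vapply(idx, function(i) {
    id <- pairs[[i]]$meta$id
    if (is.null(id)) sprintf("pair-%03d", i) else id
  }, character(1))
}

fit_provenance <- function(dataset, net_config, train_config, trn_idx) {
  list(train_ids = train_pair_ids(dataset$pairs, trn_idx),
       degradation = if (!is.null(dataset$degradation)) unclass(dataset$degradation),
       train_config = unclass(train_config),
       trained_fraction = if (!is.null(dataset$degradation)) dataset$degradation$phase_fraction)
}

accumulate_grads <- function(a, b) {
  for (nm in names(a)) {
    a[[nm]]$W <- a[[nm]]$W + b[[nm]]$W
    a[[nm]]$b <- a[[nm]]$b + b[[nm]]$b
  }
  a
}

scale_grads <- function(g, s) {
  for (nm in names(g)) {
    g[[nm]]$W <- g[[nm]]$W * s
    g[[nm]]$b <- g[[nm]]$b * s
  }
  g
}

adam_update <- function(params, grads, state, tc) {
  if (is.null(state$m)) {
    state$m <- lapply(params, function(p) list(W = p$W * 0, b = p$b * 0))
    state$v <- state$m
  }
  state$t <- state$t + 1L
  bc1 <- 1 - tc$beta1^state$t
  bc2 <- 1 - tc$beta2^state$t
  for (nm in names(params)) {
    for (fld in c("W", "b")) {
      g <- grads[[nm]][[fld]]
      state$m[[nm]][[fld]] <- tc$beta1 * state$m[[nm]][[fld]] + (1 - tc$beta1) * g
      state$v[[nm]][[fld]] <- tc$beta2 * state$v[[nm]][[fld]] + (1 - tc$beta2) * g^2
      mhat <- state$m[[nm]][[fld]] / bc1
      vhat <- state$v[[nm]][[fld]] / bc2
      params[[nm]][[fld]] <- params[[nm]][[fld]] -
        tc$learning_rate * mhat / (sqrt(vhat) + tc$epsilon)
    }
  }
  list(params = params, state = state)
}

#' @export
print.sr_fit <- function(x, ...) {
  cat(sprintf("<sr_fit> %d epochs, %s loss, final training loss %.4g (%.1f s)\n",
              nrow(x$report), x$train_config$loss,
              x$report$train_loss[nrow(x$report)], x$wall_time))
  invisible(x)
}

#' @export
tidy.sr_fit <- function(x, ...) x$report

#' @export
glance.sr_fit <- function(x, ...) {
  tibble::tibble(epochs = nrow(x$report),
                 loss = x$train_config$loss,
                 learning_rate = x$train_config$learning_rate,
                 first_loss = x$report$train_loss[1],
                 final_loss = x$report$train_loss[nrow(x$report)],
                 parameters = count_parameters(x$network),
                 wall_time = x$wall_time)
}

#' Training-loss trace plot
#' @param object An [fit()] result.
#' @param ... Unused.
#' @return A ggplot of the per-epoch training loss (and validation SSIM
#'   when recorded).
#' @export
autoplot.sr_fit <- function(object, ...) {
  ggplot2::ggplot(object$report, ggplot2::aes(x = .data$epoch, y = .data$train_loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = paste(object$train_config$loss, "training loss")) +
    ggplot2::theme_minimal()
}
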