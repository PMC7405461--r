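#' Residual U-Net architecture configuration
#'
#' Describes the 3D multiscale encoder/decoder used for single-volume
#' super-resolution: `levels` resolution scales, 3x3x3 convolutions with
#' ReLU nonlinearities (except the last layer, which produces the
#' residual update), channel count doubling per scale, 2x max-pool
#' downsampling and nearest-neighbour + convolution upsampling with
#' skip-connection concatenation. When `residual = TRUE` the learnt
#' residual is added to the input to form the output; the output is
#' projected non-negative by a final ReLU when `nonneg_output = TRUE`.
#' `residual = FALSE` reproduces a plain U-Net comparator.
#'
#' @param levels Number of resolution scales (>= 1; default 3).
#' @param base_channels Channels at the finest scale (doubling per level).
#' @param convs_per_level Convolutions per scale (default 2).
#' @param residual Learn a residual added to the input (default `TRUE`).
#' @param nonneg_output Project the output through ReLU (default `TRUE`).
#' @param upsample `"nearest_conv"` (nearest-neighbour 2x followed by a
#'   3x3x3 convolution, default). Kept as a field for provenance.
#' @param seed Integer seed for the He-uniform weight initialisation.
#' @return An object of class `network_config`.
#' @export
network_config <- function(levels = 3L, base_channels = 16L,
                           convs_per_level = 2L, residual = TRUE,
                           nonneg_output = TRUE, upsample = "nearest_conv",
                           seed = 1L) {
  levels <- as.integer(levels); base_channels <- as.integer(base_channels)
  convs_per_level <- as.integer(convs_per_level)
  stopifnot(levels >= 1L, base_channels >= 1L, convs_per_level >= 1L)
  structure(list(levels = levels, base_channels = base_channels,
                 kernel = c(3L, 3L, 3L), convs_per_level = convs_per_level,
                 residual = isTRUE(residual), nonneg_output = isTRUE(nonneg_output),
                 upsample = upsample, seed = as.integer(seed)),
            class = "network_config")
}

# ordered layer plan: list of (name, in channels, out channels)
network_layer_plan <- function(config) {
  ch <- config$base_channels * 2^(seq_len(config$levels) - 1L)
  plan <- list()
  prev <- 1L
  for (l in seq_len(config$levels)) {
    for (j in seq_len(config$convs_per_level)) {
      plan[[length(plan) + 1L]] <- list(name = sprintf("enc%d_conv%d", l, j),
                                        ci = prev, co = ch[l])
      prev <- ch[l]
    }
  }
  for (l in rev(seq_len(config$levels - 1L))) {
    plan[[length(plan) + 1L]] <- list(name = sprintf("up%d", l), ci = prev, co = ch[l])
    prev <- 2L * ch[l]   # after skip concatenation
    for (j in seq_len(config$convs_per_level)) {
      plan[[length(plan) + 1L]] <- list(name = sprintf("dec%d_conv%d", l, j),
                                        ci = prev, co = ch[l])
      prev <- ch[l]
    }
  }
  plan[[length(plan) + 1L]] <- list(name = "final", ci = prev, co = 1L)
  plan
}

#' Build a seeded residual U-Net
#'
#' Weights are initialised He-uniform (bound `sqrt(6 / fan_in)` with
#' `fan_in = 27 * in_channels`), biases at zero, drawn from a
#' deterministic stream seeded by `config$seed`.
#'
#' @param config A [network_config()].
#' @return An object of class `sr_network` holding the parameter list and
#'   its configuration.
#' @export
build_network <- function(config) {
  stopifnot(inherits(config, "network_config"))
  plan <- network_layer_plan(config)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(config$seed)
  params <- list()
  for (ly in plan) {
    fan_in <- 27L * ly$ci
    bound <- sqrt(6 / fan_in)
    params[[ly$name]] <- list(
      W = matrix(runif(fan_in * ly$co, -bound, bound), nrow = fan_in, ncol = ly$co),
      b = numeric(ly$co))
  }
  structure(list(config = config, params = params, provenance = list()),
            class = "sr_network")
}

#' @export
print.sr_network <- function(x, ...) {
  cat(sprintf("<sr_network> %d levels, %d base channels, %s parameters%s\n",
              x$config$levels, x$config$base_channels,
              format(count_parameters(x), big.mark = ","),
              if (x$config$residual) ", residual" else ""))
  invisible(x)
}

#' Number of trainable parameters
#' @param net An [build_network()] result.
#' @return Integer parameter count (weights plus biases).
#' @export
count_parameters <- function(net) {
  sum(vapply(net$params, function(p) length(p$W) + length(p$b), numeric(1)))
}

#' Save and load network checkpoints
#'
#' A checkpoint stores the parameters, the full [network_config()] and
#' any training provenance; a save/load round trip reproduces outputs
#' bit-identically.
#'
#' @param net An `sr_network`.
#' @param path Checkpoint file path.
#' @export
save_network <- function(net, path) {
  stopifnot(inherits(net, "sr_network"))
  saveRDS(net, path)
  invisible(path)
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  net <- readRDS(path)
  stopifnot(inherits(net, "sr_network"))
  net
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

as_tensor <- function(arr) {
  if (length(dim(arr)) == 3L) dim(arr) <- c(dim(arr), 1L)
  arr
}

conv_layer_fw <- function(p, x) {
  d <- dim(x)
  conv3d_fw(x, as.integer(d), p$W, p$b)
}

# Forward pass; when `keep` is TRUE the per-layer cache (conv inputs,
# post-activations, pool indices) needed by network_backward() is retained.
# List storage holds references, so caching costs no extra copies.
network_forward <- function(net, x, keep = FALSE) {
  cfg <- net$config
  p <- net$params
  x <- as_tensor(x)
  a <- x
  skips <- list()
  acts <- list()
  for (l in seq_len(cfg$levels)) {
    for (j in seq_len(cfg$convs_per_level)) {
      nm <- sprintf("enc%d_conv%d", l, j)
      z <- relu_fw_inplace(conv_layer_fw(p[[nm]], a))
      if (keep) acts[[nm]] <- list(x = a, a = z)
      a <- z
    }
    if (l < cfg$levels) {
      skips[[l]] <- a
      mp <- maxpool3d_fw(a, as.integer(dim(a)))
      if (keep) acts[[sprintf("pool%d", l)]] <- list(idx = mp$idx, in_dim = dim(a))
      a <- mp$y
    }
  }
  for (l in rev(seq_len(cfg$levels - 1L))) {
    nm <- sprintf("up%d", l)
    up_in_dim <- dim(a)
    u <- upsample3d_nn_fw(a, as.integer(dim(a)))
    z <- relu_fw_inplace(conv_layer_fw(p[[nm]], u))
    if (keep) acts[[nm]] <- list(x = u, a = z, up_in_dim = up_in_dim)
    sk <- skips[[l]]
    a <- concat4(z, as.integer(dim(z)), sk, as.integer(dim(sk)))
    for (j in seq_len(cfg$convs_per_level)) {
      nm <- sprintf("dec%d_conv%d", l, j)
      z <- relu_fw_inplace(conv_layer_fw(p[[nm]], a))
      if (keep) acts[[nm]] <- list(x = a, a = z)
      a <- z
    }
  }
  res <- conv_layer_fw(p$final, a)
  if (keep) acts$final <- list(x = a)
  pre <- if (cfg$residual) x + res else res
  out <- if (cfg$nonneg_output) relu(pre) else pre
  list(out = out, residual = res, pre = pre,
       cache = if (keep) list(acts = acts, input = x) else NULL)
}

conv_layer_bw <- function(p, x, dz, need_dx = TRUE) {
  conv3d_bw(x, as.integer(dim(x)), p$W, dz, need_dx)
}

# Backprop of dL/d(out) through the network; returns per-layer gradients
# named like the parameters. Gradient buffers are modified in place where
# the reference is unique.
network_backward <- function(net, fw, dout) {
  cfg <- net$config
  p <- net$params
  acts <- fw$cache$acts
  grads <- list()
  dpre <- if (cfg$nonneg_output) dout * (fw$pre > 0) else dout
  # residual branch: d res = dpre (the skip-to-input contributes only to dx)
  bw <- conv_layer_bw(p$final, acts$final$x, dpre)
  grads$final <- list(W = bw$dW, b = bw$db)
  da <- bw$dx
  ch <- cfg$base_channels * 2^(seq_len(cfg$levels) - 1L)
  dskips <- list()
  for (l in seq_len(cfg$levels - 1L)) {
    for (j in rev(seq_len(cfg$convs_per_level))) {
      nm <- sprintf("dec%d_conv%d", l, j)
      dz <- relu_bw_inplace(da, acts[[nm]]$a)
      bw <- conv_layer_bw(p[[nm]], acts[[nm]]$x, dz)
      grads[[nm]] <- list(W = bw$dW, b = bw$db)
      da <- bw$dx
    }
    # split the concatenation: first ch[l] channels fed from the up conv,
    # the rest from the skip connection
    d4 <- dim(da)
    dup <- da[, , , seq_len(ch[l]), drop = FALSE]
    dskips[[l]] <- da[, , , ch[l] + seq_len(d4[4] - ch[l]), drop = FALSE]
    nm <- sprintf("up%d", l)
    dz <- relu_bw_inplace(dup, acts[[nm]]$a)
    bw <- conv_layer_bw(p[[nm]], acts[[nm]]$x, dz)
    grads[[nm]] <- list(W = bw$dW, b = bw$db)
    da <- upsample3d_nn_bw(bw$dx, as.integer(acts[[nm]]$up_in_dim))
  }
  for (l in rev(seq_len(cfg$levels))) {
    if (l < cfg$levels) {
      pl <- acts[[sprintf("pool%d", l)]]
      da <- maxpool3d_bw(pl$idx, da, as.integer(pl$in_dim))
      da <- da + dskips[[l]]
    }
    for (j in rev(seq_len(cfg$convs_per_level))) {
      nm <- sprintf("enc%d_conv%d", l, j)
      dz <- relu_bw_inplace(da, acts[[nm]]$a)
      # the input gradient of the first encoder conv is never consumed
      need <- !(l == 1L && j == 1L)
      bw <- conv_layer_bw(p[[nm]], acts[[nm]]$x, dz, need_dx = need)
      grads[[nm]] <- list(W = bw$dW, b = bw$db)
      da <- bw$dx
    }
  }
  grads
}

#' Apply the network to a magnitude volume
#'
#' Pads the grid symmetrically so every axis is divisible by
#' `2^(levels - 1)`, runs the forward pass, and crops back. Output values
#' are non-negative when the configuration projects them so; the output
#' grid equals the input grid.
#'
#' @param net An [build_network()] (or [fit()]-trained) network.
#' @param vol A [volume][as_volume] with non-negative intensities,
#'   conventionally normalized to `[0, 1]`.
#' @param detail If `TRUE`, also return the pre-projection residual.
#' @return A `volume` (or, with `detail = TRUE`, a list with `volume` and
#'   `residual`).
#' @export
super_resolve <- function(net, vol, detail = FALSE) {
  stopifnot(inherits(net, "sr_network"), is_volume(vol))
  if (any(vol$data < 0)) abort("super_resolve() expects non-negative magnitude input.")
  m <- 2^(net$config$levels - 1L)
  d <- dim(vol$data)
  dpad <- as.integer(ceiling(d / m) * m)
  x <- if (all(dpad == d)) vol$data else crop_pad_array(vol$data, dpad)
  fw <- network_forward(net, x, keep = FALSE)
  out <- fw$out
  dim(out) <- dpad
  res <- fw$residual
  dim(res) <- dpad
  if (!all(dpad == d)) {
    out <- crop_pad_array(out, d)
    res <- crop_pad_array(res, d)
  }
  v <- as_volume(out, vol$spacing)
  if (detail) list(volume = v, residual = res) else v
}
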