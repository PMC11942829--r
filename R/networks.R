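#' Denoising network architectures
#'
#' Four convolutional denoisers for scintigraphic images:
#'
#' * **dncnn** — a plain 8-layer denoising CNN: input conv, six
#'   conv+BN+ReLU blocks, output conv; no pooling, padding preserves the
#'   spatial size throughout.
#' * **udncnn** — the same 8-conv backbone arranged as a U: 2x2 max
#'   pooling with stored indices in the contraction half, index-preserving
#'   2x2 unpooling in the expansion half, and contraction features merged
#'   into the expansion path as an element-wise sum divided by 2.
#' * **dudncnn** — the U-shaped skeleton with pooling/unpooling replaced
#'   by dilated convolutions; the per-layer dilation is
#'   `2^(kappa - iota)` where `kappa` counts poolings and `iota`
#'   unpoolings that the U-shaped network would have applied so far, so
#'   the receptive field of each layer matches its pooled counterpart
#'   without adding parameters.
#' * **attngan** — an attention-gated encoder/decoder generator (four
#'   pool/unpool stages with CBAM attention after each stage) plus a
#'   patch discriminator producing a score map rather than one scalar.
#'
#' @name denoise_models
NULL

#' Network configuration
#'
#' @param family One of `"dncnn"`, `"udncnn"`, `"dudncnn"`, `"attngan"`.
#' @param depth Total number of convolutional layers for the three DnCNN
#'   variants (default 8: input conv + 6 middle blocks + output conv).
#' @param filters Feature channels per conv layer (default 64).
#' @param kernel Convolution kernel size (odd; default 3).
#' @param in_channels,out_channels Image channels. Native scintigraphy
#'   mode is single-channel; 3 reproduces an RGB-replicated mode.
#' @param pool_positions Conv-layer indices after which the U-shaped
#'   variants pool; the matching unpooling happens after layer
#'   `depth - p`. Default `c(2, 3)` gives two balanced stages.
#' @param stages Down/upsampling stages for the attngan generator.
#' @return A `network_config` list.
#' @export
network_config <- function(family = c("dncnn", "udncnn", "dudncnn", "attngan"),
                           depth = 8L, filters = 64L, kernel = 3L,
                           in_channels = 1L, out_channels = in_channels,
                           pool_positions = c(2L, 3L), stages = 4L) {
  family <- match.arg(family)
  depth <- as.integer(depth); filters <- as.integer(filters)
  if (depth < 3) stop("depth must be at least 3")
  if (kernel %% 2 != 1) stop("kernel must be odd")
  pool_positions <- sort(as.integer(pool_positions))
  if (length(pool_positions) &&
      (min(pool_positions) < 2 || max(pool_positions) >= depth - max(pool_positions) ||
       max(pool_positions) > depth - 1))
    stop("pool positions must be balanced within the middle layers")
  cfg <- list(family = family, depth = depth, filters = filters,
              kernel = kernel, in_channels = as.integer(in_channels),
              out_channels = as.integer(out_channels),
              pool_positions = pool_positions,
              unpool_positions = depth - rev(pool_positions),
              stages = as.integer(stages))
  class(cfg) <- "network_config"
  cfg
}

#' Dilation factor replacing pooling
#'
#' The dilated variant replaces each 2x2 pooling with a doubling of the
#' dilation: a layer that the U-shaped network would run after `kappa`
#' poolings and `iota` unpoolings uses dilation `2^(kappa - iota)`, so one
#' pooling level gives the stated dilation factor of 2 and the receptive
#' field matches the pooled network's.
#'
#' @param kappa Number of poolings applied so far (`>= iota`).
#' @param iota Number of unpoolings applied so far.
#' @return Integer dilation factor, `>= 1`.
#' @export
dilation_for_layer <- function(kappa, iota) {
  if (iota > kappa || kappa < 0 || iota < 0)
    stop("require kappa >= iota >= 0")
  as.integer(2^(kappa - iota))
}

# Kaiming-uniform init as used by standard conv implementations.
init_conv <- function(k, cin, cout) {
  fan_in <- k * k * cin
  bw <- sqrt(6 / fan_in)
  w <- array(stats::runif(k * k * cin * cout, -bw, bw), dim = c(k, k, cin, cout))
  bb <- 1 / sqrt(fan_in)
  list(w = w, b = stats::runif(cout, -bb, bb), stride = 1L, pad = (k - 1L) %/% 2L,
       dil = 1L)
}

init_bn <- function(c) {
  list(gamma = rep(1, c), beta = rep(0, c), rm = rep(0, c), rv = rep(1, c))
}

init_dense <- function(cin, cout) {
  bw <- sqrt(6 / cin)
  list(w = matrix(stats::runif(cin * cout, -bw, bw), cout, cin))
}

new_net <- function(cfg) {
  net <- new.env(parent = emptyenv())
  net$config <- cfg
  net$family <- cfg$family
  net$layers <- list()
  class(net) <- "denoiser_net"
  net
}

#' Build a denoising network
#'
#' Dispatches on `config$family`. Construction is seeded by `seed`, so the
#' same `(config, seed)` always yields identical parameters.
#'
#' @param config A [network_config()].
#' @param seed Integer seed for weight initialization.
#' @return A `denoiser_net` object.
#' @export
build_denoiser <- function(config, seed = 1L) {
  switch(config$family,
    dncnn = build_dncnn(config, seed),
    udncnn = build_udncnn(config, seed),
    dudncnn = build_dudncnn(config, seed),
    attngan = build_attn_generator(config, seed))
}

# Shared 8-conv skeleton: conv1 (in -> F), conv2..conv(depth-1) (F -> F,
# each with BN), conv(depth) (F -> out). Dilation schedule per family.
build_backbone <- function(cfg, seed, dilations) {
  net <- new_net(cfg)
  with_seed(seed, {
    k <- cfg$kernel; f <- cfg$filters; d <- cfg$depth
    ls <- list()
    ls$conv1 <- init_conv(k, cfg$in_channels, f)
    for (j in 2:(d - 1)) {
      ls[[paste0("conv", j)]] <- init_conv(k, f, f)
      ls[[paste0("bn", j)]] <- init_bn(f)
    }
    ls[[paste0("conv", d)]] <- init_conv(k, f, cfg$out_channels)
    for (j in seq_len(d)) {
      nm <- paste0("conv", j)
      ls[[nm]]$dil <- dilations[j]
      ls[[nm]]$pad <- dilations[j] * (k - 1L) %/% 2L
    }
    net$layers <- ls
  })
  net
}

#' @rdname denoise_models
#' @inheritParams build_denoiser
#' @export
build_dncnn <- function(config, seed = 1L) {
  if (config$family != "dncnn") stop("config family must be 'dncnn'")
  build_backbone(config, seed, rep(1L, config$depth))
}

#' @rdname denoise_models
#' @export
build_udncnn <- function(config, seed = 1L) {
  if (config$family != "udncnn") stop("config family must be 'udncnn'")
  build_backbone(config, seed, rep(1L, config$depth))
}

#' @rdname denoise_models
#' @export
build_dudncnn <- function(config, seed = 1L) {
  if (config$family != "dudncnn") stop("config family must be 'dudncnn'")
  d <- config$depth
  dil <- integer(d)
  for (j in seq_len(d)) {
    kap <- sum(config$pool_positions < j)
    iot <- sum(config$unpool_positions < j)
    dil[j] <- dilation_for_layer(kap, iot)
  }
  build_backbone(config, seed, dil)
}

# Forward pass of the three DnCNN variants on an existing tape.
backbone_forward <- function(tp, net, x_id) {
  cfg <- net$config
  d <- cfg$depth
  u_shaped <- cfg$family %in% c("udncnn", "dudncnn")
  pooled <- cfg$family == "udncnn"
  skips <- list()     # pre-pool activations by pool position
  pool_nodes <- list()
  h <- tp_relu(tp, tp_conv(tp, net, "conv1", x_id))
  for (j in 2:(d - 1)) {
    h <- tp_conv(tp, net, paste0("conv", j), h)
    h <- tp_bn(tp, net, paste0("bn", j), h)
    h <- tp_relu(tp, h)
    if (u_shaped && j %in% cfg$pool_positions) {
      skips[[as.character(j)]] <- h
      if (pooled) {
        pn <- tp_pool(tp, h)
        pool_nodes[[as.character(j)]] <- pn
        h <- pn
      }
    }
    if (u_shaped && j %in% cfg$unpool_positions &&
        length(cfg$pool_positions)) {
      # unpool after layer j pairs with the pool after layer d - j,
      # so inner poolings are undone first
      p <- d - j
      if (pooled) h <- tp_unpool(tp, h, pool_nodes[[as.character(p)]])
      h <- tp_axpy(tp, h, skips[[as.character(p)]], 0.5, 0.5)
    }
  }
  tp_conv(tp, net, paste0("conv", d), h)
}

#' @rdname denoise_models
#' @export
build_attn_generator <- function(config, seed = 1L) {
  if (config$family != "attngan") stop("config family must be 'attngan'")
  net <- new_net(config)
  with_seed(seed, {
    f <- config$filters; s <- config$stages
    ls <- list()
    ls$enc0 <- init_conv(3L, config$in_channels, f)
    fs <- f * 2^(0:s)          # 64 128 256 512 1024 for defaults
    for (i in seq_len(s)) {
      ls[[paste0("enc", i)]] <- init_conv(3L, fs[i], fs[i + 1])
      ls[[paste0("enc", i, "_ca1")]] <- init_dense(fs[i + 1], max(fs[i + 1] %/% 8L, 1L))
      ls[[paste0("enc", i, "_ca2")]] <- init_dense(max(fs[i + 1] %/% 8L, 1L), fs[i + 1])
      sa <- init_conv(7L, 2L, 1L)
      ls[[paste0("enc", i, "_sa")]] <- sa
    }
    for (i in seq(s, 1)) {
      up <- init_conv(2L, fs[i], fs[i + 1])   # underlying conv of convT
      up$stride <- 2L; up$pad <- 0L
      up$b <- stats::runif(fs[i], -1 / sqrt(fs[i + 1] * 4), 1 / sqrt(fs[i + 1] * 4))
      ls[[paste0("dec", i, "_up")]] <- up
      ls[[paste0("dec", i)]] <- init_conv(3L, fs[i], fs[i])
      ls[[paste0("dec", i, "_ca1")]] <- init_dense(fs[i], max(fs[i] %/% 8L, 1L))
      ls[[paste0("dec", i, "_ca2")]] <- init_dense(max(fs[i] %/% 8L, 1L), fs[i])
      ls[[paste0("dec", i, "_sa")]] <- init_conv(7L, 2L, 1L)
    }
    ls$out <- init_conv(3L, f, config$out_channels)
    net$layers <- ls
  })
  net
}

# Convolutional block attention: channel gate (shared two-layer MLP over
# global average and max pools, sigmoid) then spatial gate (7x7 conv over
# channel-wise average and max maps, sigmoid), both multiplicative.
cbam_forward <- function(tp, net, prefix, h) {
  pa <- tp_gp_avg(tp, h)
  pm <- tp_gp_max(tp, h)
  ha <- tp_dense(tp, net, paste0(prefix, "_ca2"),
                 tp_relu(tp, tp_dense(tp, net, paste0(prefix, "_ca1"), pa)))
  hm <- tp_dense(tp, net, paste0(prefix, "_ca2"),
                 tp_relu(tp, tp_dense(tp, net, paste0(prefix, "_ca1"), pm)))
  gate <- tp_sigmoid(tp, tp_axpy(tp, ha, hm, 1, 1))
  hc <- tp_scale_channel(tp, h, gate)
  sa <- tp_ch_avgmap(tp, hc)
  sm <- tp_ch_maxmap(tp, hc)
  smap <- tp_sigmoid(tp, tp_conv(tp, net, paste0(prefix, "_sa"),
                                 tp_concat_ch(tp, sa, sm)))
  tp_scale_spatial(tp, hc, smap)
}

attn_generator_forward <- function(tp, net, x_id) {
  cfg <- net$config
  s <- cfg$stages
  d <- dim(node_value(tp, x_id))
  if (d[1] %% 2^s != 0 || d[2] %% 2^s != 0)
    stop("input side must be divisible by ", 2^s, " for the attngan generator")
  h <- tp_relu(tp, tp_conv(tp, net, "enc0", x_id))
  for (i in seq_len(s)) {
    h <- tp_relu(tp, tp_conv(tp, net, paste0("enc", i), h))
    h <- tp_pool(tp, h)
    h <- cbam_forward(tp, net, paste0("enc", i), h)
  }
  for (i in seq(s, 1)) {
    h <- tp_convT(tp, net, paste0("dec", i, "_up"), h)
    h <- tp_relu(tp, tp_conv(tp, net, paste0("dec", i), h))
    h <- cbam_forward(tp, net, paste0("dec", i), h)
  }
  tp_conv(tp, net, "out", h)
}

#' Patch discriminator for the adversarial denoiser
#'
#' A stack of strided convolutions with increasing feature depth mapping
#' an image to a patch-score map (one logit per receptive-field patch).
#' With kernel 4, pad 1 and strides (2, 2, 2, 1, 1), a 256 x 256 input
#' maps to a 30 x 30 score map.
#'
#' @param config A [network_config()] with `family = "attngan"`.
#' @param seed Integer seed for weight initialization.
#' @return A `denoiser_net` acting as discriminator.
#' @export
build_pixel_discriminator <- function(config, seed = 1L) {
  if (config$family != "attngan") stop("config family must be 'attngan'")
  net <- new_net(config)
  net$role <- "discriminator"
  with_seed(seed + 7L, {
    f <- config$filters
    specs <- list(
      c(config$in_channels, f, 2L),
      c(f, 2L * f, 2L),
      c(2L * f, 4L * f, 2L),
      c(4L * f, 8L * f, 1L),
      c(8L * f, 1L, 1L))
    ls <- list()
    for (i in seq_along(specs)) {
      l <- init_conv(4L, specs[[i]][1], specs[[i]][2])
      l$stride <- specs[[i]][3]; l$pad <- 1L
      ls[[paste0("d", i)]] <- l
      if (i >= 2 && i <= 4) ls[[paste0("dbn", i)]] <- init_bn(specs[[i]][2])
    }
    net$layers <- ls
  })
  net
}

discriminator_forward <- function(tp, net, x_id) {
  h <- tp_lrelu(tp, tp_conv(tp, net, "d1", x_id))
  for (i in 2:4) {
    h <- tp_conv(tp, net, paste0("d", i), h)
    h <- tp_bn(tp, net, paste0("dbn", i), h)
    h <- tp_lrelu(tp, h)
  }
  tp_conv(tp, net, "d5", h)
}

# Single entry point used by training and prediction.
net_forward <- function(net, x, train = TRUE) {
  tp <- new_tape(train)
  x_id <- tp_input(tp, x)
  out <- if (identical(net$role, "discriminator"))
    discriminator_forward(tp, net, x_id)
  else if (net$family == "attngan")
    attn_generator_forward(tp, net, x_id)
  else
    backbone_forward(tp, net, x_id)
  list(tape = tp, x_id = x_id, out_id = out, y = node_value(tp, out))
}

#' Run a network on a batch of images
#'
#' Evaluation-mode forward pass (batch statistics frozen). Inputs are
#' processed in chunks to bound memory.
#'
#' @param net A `denoiser_net`.
#' @param x Array `(H, W, C, N)` or a single `H x W` matrix.
#' @param chunk Images per forward chunk.
#' @return Array of the same batch shape (matrix in, matrix out).
#' @export
net_predict <- function(net, x, chunk = 4L) {
  single <- is.matrix(x)
  if (single) x <- array(x, dim = c(nrow(x), ncol(x), 1, 1))
  N <- dim(x)[4]
  out <- NULL
  for (s in seq(1, N, by = chunk)) {
    e <- min(s + chunk - 1, N)
    fw <- net_forward(net, x[, , , s:e, drop = FALSE], train = FALSE)
    if (is.null(out))
      out <- array(0, dim = c(dim(fw$y)[1:3], N))
    out[, , , s:e] <- fw$y
  }
  if (single) matrix(out[, , 1, 1], dim(out)[1], dim(out)[2]) else out
}

# ---- parameter utilities ---------------------------------------------

param_fields <- c("w", "b", "gamma", "beta")

#' Number of trainable parameters
#'
#' @param net A `denoiser_net`.
#' @return Integer count of trainable parameters (conv weights and
#'   biases, batch-norm scales and shifts; running statistics excluded).
#' @export
n_parameters <- function(net) {
  tot <- 0
  for (l in net$layers)
    for (f in param_fields)
      if (!is.null(l[[f]])) tot <- tot + length(l[[f]])
  as.integer(tot)
}

#' Count convolutional layers of a network
#' @param net A `denoiser_net`.
#' @return Number of convolution (and transposed-convolution) layers.
#' @export
n_conv_layers <- function(net) {
  sum(vapply(net$layers, function(l) !is.null(l$w) && length(dim(l$w)) == 4,
             logical(1)))
}

#' @export
print.denoiser_net <- function(x, ...) {
  role <- if (identical(x$role, "discriminator")) "discriminator" else "denoiser"
  cat(sprintf("%s network (%s): %d conv layers, %s parameters\n",
              x$family, role, n_conv_layers(x),
              format(n_parameters(x), big.mark = ",")))
  invisible(x)
}

# Deep-copy a network (environments are reference objects).
clone_net <- function(net) {
  out <- new_net(net$config)
  out$family <- net$family
  out$layers <- net$layers
  if (!is.null(net$role)) out$role <- net$role
  out
}
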