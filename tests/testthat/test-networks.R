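test_that("network_config validates its arguments", {
  cfg <- network_config("dncnn")
  expect_identical(cfg$depth, 8L)
  expect_identical(cfg$filters, 64L)
  expect_identical(cfg$kernel, 3L)
  expect_identical(network_config("udncnn")$unpool_positions, c(5L, 6L))
  expect_error(network_config("dncnn", depth = 2), "depth")
  expect_error(network_config("dncnn", kernel = 4), "odd")
  expect_error(network_config("udncnn", pool_positions = c(1, 2)), "pool")
  expect_error(network_config("nonsense"))
})

test_that("builders are deterministic and family-checked", {
  cfg <- network_config("dncnn", filters = 4)
  a <- build_denoiser(cfg, seed = 3)
  b <- build_denoiser(cfg, seed = 3)
  expect_identical(a$layers, b$layers)
  c <- build_denoiser(cfg, seed = 4)
  expect_false(identical(a$layers$conv1$w, c$layers$conv1$w))
  expect_error(build_dncnn(network_config("udncnn", filters = 4)), "family")
  expect_error(build_udncnn(network_config("dncnn", filters = 4)), "family")
})

test_that("DnCNN has exactly 8 conv layers and preserves spatial size", {
  net <- build_denoiser(network_config("dncnn", filters = 4), 1)
  expect_identical(n_conv_layers(net), 8L)
  for (H in c(8L, 16L, 24L)) {
    x <- array(runif(H * H), dim = c(H, H, 1, 1))
    y <- net_predict(net, x)
    expect_identical(dim(y), dim(x))
  }
})

test_that("the middle six layers carry BN, the ends do not", {
  net <- build_denoiser(network_config("dncnn", filters = 4), 1)
  nms <- names(net$layers)
  expect_true(all(paste0("bn", 2:7) %in% nms))
  expect_false("bn1" %in% nms)
  expect_false("bn8" %in% nms)
})

test_that("parameter count matches the closed-form conv + BN formula", {
  f <- 4L
  net <- build_denoiser(network_config("dncnn", filters = f), 1)
  convs <- (9 * 1 * f + f) + 6 * (9 * f * f + f) + (9 * f * 1 + 1)
  bns <- 6 * (2 * f)   # gamma + beta (running stats are not parameters)
  expect_identical(n_parameters(net), as.integer(convs + bns))
})

test_that("DnCNN, UDnCNN and DUDnCNN have identical parameter counts", {
  counts <- vapply(c("dncnn", "udncnn", "dudncnn"), function(fam)
    n_parameters(build_denoiser(network_config(fam, filters = 8), 1)),
    integer(1))
  expect_identical(unname(counts), rep(counts[[1]], 3))
})

test_that("index-storing unpooling restores argmax positions", {
  # one-hot image: pool keeps the hot pixel, unpool returns it exactly
  x <- array(0, dim = c(8, 8, 1, 1))
  x[3, 6, 1, 1] <- 5
  p <- rn$.maxpool2_fwd(x)
  u <- rn$.maxunpool2_fwd(p$y, p$idx, 8L, 8L)
  expect_identical(u, x)

  # generic input: every retained maximum returns to its argmax position
  set.seed(9)
  x2 <- array(runif(8 * 8 * 2 * 2), dim = c(8, 8, 2, 2))
  p2 <- rn$.maxpool2_fwd(x2)
  u2 <- rn$.maxunpool2_fwd(p2$y, p2$idx, 8L, 8L)
  nz <- which(u2 != 0)
  expect_true(all(u2[nz] == x2[nz]))
  expect_identical(sum(u2 != 0), length(p2$y))
})

test_that("UDnCNN and DUDnCNN forwards preserve the input size", {
  for (fam in c("udncnn", "dudncnn")) {
    net <- build_denoiser(network_config(fam, filters = 4), 1)
    x <- array(runif(16 * 16), dim = c(16, 16, 1, 1))
    expect_identical(dim(net_predict(net, x)), dim(x))
  }
})

test_that("skip merge (x + s)/2 is the identity on equal tensors", {
  tp <- rn$new_tape(train = FALSE)
  x <- array(runif(32), dim = c(4, 4, 2, 1))
  a <- rn$tp_input(tp, x)
  m <- rn$tp_axpy(tp, a, a, 0.5, 0.5)
  expect_equal(rn$node_value(tp, m), x, tolerance = 1e-12)
})

test_that("dilation follows 2^(kappa - iota) with the 1,1,2,4,4,2,1,1 schedule", {
  expect_identical(dilation_for_layer(0, 0), 1L)
  expect_identical(dilation_for_layer(1, 0), 2L)
  expect_identical(dilation_for_layer(2, 0), 4L)
  expect_identical(dilation_for_layer(2, 1), 2L)
  expect_identical(dilation_for_layer(2, 2), 1L)
  expect_error(dilation_for_layer(1, 2), "kappa")

  net <- build_denoiser(network_config("dudncnn", filters = 4), 1)
  dil <- vapply(paste0("conv", 1:8), function(nm) net$layers[[nm]]$dil,
                integer(1))
  expect_identical(unname(dil), c(1L, 1L, 2L, 4L, 4L, 2L, 1L, 1L))
})

test_that("dilated 3x3 kernels cover 5x5 (d=2) and 7x7 (d=3) footprints", {
  # impulse-response oracle: an all-ones kernel on a centered impulse
  # marks exactly the footprint
  for (cfg in list(c(d = 2L, fp = 5L), c(d = 3L, fp = 7L))) {
    x <- array(0, dim = c(15, 15, 1, 1)); x[8, 8, 1, 1] <- 1
    w <- array(1, dim = c(3, 3, 1, 1))
    pad <- cfg[["d"]]
    y <- rn$.conv2d_fwd(x, w, 0, 1L, pad, cfg[["d"]])
    hit <- which(y[, , 1, 1] != 0, arr.ind = TRUE)
    expect_identical(max(hit[, 1]) - min(hit[, 1]) + 1L, cfg[["fp"]])
    expect_identical(max(hit[, 2]) - min(hit[, 2]) + 1L, cfg[["fp"]])
    expect_identical(nrow(hit), 9L)  # 3x3 taps with holes
  }
})

test_that("attention generator preserves shape and CBAM gates multiplicatively", {
  cfg <- network_config("attngan", filters = 4)
  net <- build_denoiser(cfg, 1)
  x <- array(runif(32 * 32), dim = c(32, 32, 1, 1))
  expect_identical(dim(net_predict(net, x)), dim(x))

  # all-zero input stays all-zero through the CBAM gates when biases are
  # removed (multiplicative gating cannot create signal)
  net0 <- rn$clone_net(net)
  for (nm in names(net0$layers)) {
    if (!is.null(net0$layers[[nm]]$b)) net0$layers[[nm]]$b[] <- 0
  }
  z <- net_predict(net0, array(0, dim = c(16, 16, 1, 1)))
  expect_equal(max(abs(z)), 0, tolerance = 1e-12)
})

test_that("discriminator halves three times then crops twice: 64 -> 6", {
  cfg <- network_config("attngan", filters = 4)
  disc <- build_pixel_discriminator(cfg, 1)
  x <- array(runif(64 * 64 * 2), dim = c(64, 64, 1, 2))
  y <- rn$net_predict(disc, x)
  # stride arithmetic oracle: 64 ->32 ->16 ->8 ->(k4 s1 p1) 7 -> 6
  s2 <- function(n) as.integer(floor((n + 2 * 1 - 4) / 2) + 1)
  s1 <- function(n) as.integer(n + 2 * 1 - 4 + 1)
  side <- s1(s1(s2(s2(s2(64L)))))
  expect_identical(dim(y), c(side, side, 1L, 2L))
  expect_identical(dim(y)[1], 6L)
  expect_true(all(is.finite(y)))
  expect_error(net_predict(disc, array(0, dim = c(8, 8, 1, 1))), "small")
})

test_that("net_predict chunking does not change results", {
  net <- build_denoiser(network_config("dncnn", filters = 4), 1)
  x <- array(runif(8 * 8 * 1 * 5), dim = c(8, 8, 1, 5))
  y1 <- net_predict(net, x, chunk = 1L)
  y5 <- net_predict(net, x, chunk = 5L)
  expect_equal(y1, y5, tolerance = 1e-6)
})
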