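# Minimal reverse-mode tape used by the denoising networks.
#
# A forward pass records operation nodes on a tape held in an
# environment; `tape_backward()` walks the tape in reverse, applying each
# op's vector-Jacobian product and accumulating gradients both for
# activations (by node id) and for layer parameters (by layer name and
# field). Activations live in R arrays laid out (H, W, C, N); the heavy
# convolution/pooling kernels are compiled.

new_tape <- function(train = TRUE) {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- list()
  tp$n <- 0L
  tp$train <- train
  tp
}

emit <- function(tp, op, inputs, value, cache = NULL, layer = NULL) {
  tp$n <- tp$n + 1L
  tp$nodes[[tp$n]] <- list(op = op, inputs = inputs, value = value,
                           cache = cache, layer = layer)
  tp$n
}

node_value <- function(tp, id) {
  force(id)  # nested tp_* calls must append their node first
  tp$nodes[[id]]$value
}

tp_input <- function(tp, x) emit(tp, "input", integer(0), x)

# ---- parameterized ops ------------------------------------------------

tp_conv <- function(tp, net, lname, id) {
  l <- net$layers[[lname]]
  x <- node_value(tp, id)
  y <- .conv2d_fwd(x, l$w, l$b, l$stride, l$pad, l$dil)
  emit(tp, "conv", id, y, cache = list(dimx = dim(x)), layer = lname)
}

# Transposed convolution (stride = kernel = 2 in the decoders): the
# forward pass is the input-gradient of an ordinary strided convolution.
tp_convT <- function(tp, net, lname, id) {
  l <- net$layers[[lname]]
  x <- node_value(tp, id)
  d <- dim(x)
  Hout <- d[1] * l$stride; Wout <- d[2] * l$stride
  y <- .conv2d_bwd_input(x, l$w, l$stride, l$pad, 1L, Hout, Wout)
  dy <- dim(y)
  y <- y + array(rep(rep(l$b, each = dy[1] * dy[2]), dy[4]), dim = dy)
  emit(tp, "convT", id, y, cache = list(dimx = d), layer = lname)
}

tp_bn <- function(tp, net, lname, id) {
  l <- net$layers[[lname]]
  x <- node_value(tp, id)
  d <- dim(x)
  xp <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = d[3])
  if (tp$train) {
    mu <- colMeans(xp)
    v <- colMeans(xp * xp) - mu * mu
    v[v < 0] <- 0
    mom <- 0.1
    net$layers[[lname]]$rm <- (1 - mom) * l$rm + mom * mu
    net$layers[[lname]]$rv <- (1 - mom) * l$rv + mom * v
  } else {
    mu <- l$rm; v <- l$rv
  }
  istd <- 1 / sqrt(v + 1e-5)
  m <- nrow(xp)
  xh <- (xp - matrix(mu, m, d[3], byrow = TRUE)) *
    matrix(istd, m, d[3], byrow = TRUE)
  yp <- xh * matrix(l$gamma, m, d[3], byrow = TRUE) +
    matrix(l$beta, m, d[3], byrow = TRUE)
  y <- aperm(array(yp, d[c(1, 2, 4, 3)]), c(1, 2, 4, 3))
  emit(tp, "bn", id, y,
       cache = list(xh = xh, istd = istd, d = d), layer = lname)
}

tp_dense <- function(tp, net, lname, id) {
  # x is a (C_in x N) matrix; y = W x
  l <- net$layers[[lname]]
  x <- node_value(tp, id)
  emit(tp, "dense", id, l$w %*% x, cache = list(x = x), layer = lname)
}

# ---- parameter-free ops ----------------------------------------------

tp_relu <- function(tp, id) {
  x <- node_value(tp, id)
  y <- x; y[y < 0] <- 0
  emit(tp, "relu", id, y, cache = list(mask = x > 0))
}

tp_lrelu <- function(tp, id, alpha = 0.2) {
  x <- node_value(tp, id)
  y <- ifelse(x > 0, x, alpha * x)
  dim(y) <- dim(x)
  emit(tp, "lrelu", id, y, cache = list(mask = x > 0, alpha = alpha))
}

tp_sigmoid <- function(tp, id) {
  y <- 1 / (1 + exp(-node_value(tp, id)))
  emit(tp, "sigmoid", id, y, cache = NULL)
}

tp_pool <- function(tp, id) {
  x <- node_value(tp, id)
  r <- .maxpool2_fwd(x)
  emit(tp, "pool", id, r$y,
       cache = list(idx = r$idx, H = dim(x)[1], W = dim(x)[2]))
}

tp_unpool <- function(tp, id, pool_node) {
  force(pool_node)
  x <- node_value(tp, id)
  pc <- tp$nodes[[pool_node]]$cache
  y <- .maxunpool2_fwd(x, pc$idx, pc$H, pc$W)
  emit(tp, "unpool", id, y,
       cache = list(idx = pc$idx, Ho = dim(x)[1], Wo = dim(x)[2]))
}

tp_axpy <- function(tp, ida, idb, ca = 0.5, cb = 0.5) {
  y <- ca * node_value(tp, ida) + cb * node_value(tp, idb)
  emit(tp, "axpy", c(ida, idb), y, cache = list(ca = ca, cb = cb))
}

tp_gp_avg <- function(tp, id) {
  x <- node_value(tp, id); d <- dim(x)
  y <- matrix(colMeans(matrix(x, d[1] * d[2])), d[3], d[4])
  emit(tp, "gp_avg", id, y, cache = list(d = d))
}

tp_gp_max <- function(tp, id) {
  x <- node_value(tp, id); d <- dim(x)
  xm <- matrix(x, d[1] * d[2])
  am <- max.col(t(xm), ties.method = "first")   # argmax per (c,n) column
  y <- matrix(xm[cbind(am, seq_along(am))], d[3], d[4])
  emit(tp, "gp_max", id, y, cache = list(d = d, am = am))
}

tp_scale_channel <- function(tp, idx_x, idx_g) {
  x <- node_value(tp, idx_x); g <- node_value(tp, idx_g)
  d <- dim(x)
  y <- x * array(rep(as.vector(g), each = d[1] * d[2]), dim = d)
  emit(tp, "scale_channel", c(idx_x, idx_g), y, cache = list(d = d))
}

tp_ch_avgmap <- function(tp, id) {
  x <- node_value(tp, id); d <- dim(x)
  # mean over channels -> (H, W, 1, N)
  xm <- array(x, dim = c(d[1] * d[2], d[3], d[4]))
  y <- array(apply(xm, 3, rowMeans), dim = c(d[1], d[2], 1, d[4]))
  emit(tp, "ch_avgmap", id, y, cache = list(d = d))
}

tp_ch_maxmap <- function(tp, id) {
  x <- node_value(tp, id); d <- dim(x)
  xm <- array(x, dim = c(d[1] * d[2], d[3], d[4]))
  y <- array(0, dim = c(d[1] * d[2], d[4]))
  am <- matrix(1L, d[1] * d[2], d[4])
  for (n in seq_len(d[4])) {
    sl <- xm[, , n, drop = TRUE]
    if (is.null(dim(sl))) sl <- matrix(sl, ncol = d[3])
    am[, n] <- max.col(sl, ties.method = "first")
    y[, n] <- sl[cbind(seq_len(d[1] * d[2]), am[, n])]
  }
  emit(tp, "ch_maxmap", id, array(y, dim = c(d[1], d[2], 1, d[4])),
       cache = list(d = d, am = am))
}

tp_concat_ch <- function(tp, ida, idb) {
  a <- node_value(tp, ida); b <- node_value(tp, idb)
  da <- dim(a); db <- dim(b)
  y <- array(0, dim = c(da[1], da[2], da[3] + db[3], da[4]))
  y[, , seq_len(da[3]), ] <- a
  y[, , da[3] + seq_len(db[3]), ] <- b
  emit(tp, "concat_ch", c(ida, idb), y, cache = list(ca = da[3], cb = db[3]))
}

tp_scale_spatial <- function(tp, idx_x, idx_g) {
  x <- node_value(tp, idx_x); g <- node_value(tp, idx_g)
  d <- dim(x)
  y <- x * g[, , rep(1, d[3]), , drop = FALSE]
  emit(tp, "scale_spatial", c(idx_x, idx_g), y, cache = list(d = d))
}

# ---- backward ---------------------------------------------------------

accum <- function(lst, id, g) {
  if (is.null(lst[[id]])) lst[[id]] <- g else lst[[id]] <- lst[[id]] + g
  lst
}

# Walk the tape backwards from `seed_id` with upstream gradient `gseed`.
# Returns list(param_grads = nested list by layer/field,
#              input_grads = grads at "input" nodes keyed by node id).
tape_backward <- function(tp, net, seed_id, gseed) {
  grads <- vector("list", tp$n)
  grads[[seed_id]] <- gseed
  pg <- list()
  add_pg <- function(lname, field, g) {
    if (is.null(pg[[lname]])) pg[[lname]] <<- list()
    cur <- pg[[lname]][[field]]
    pg[[lname]][[field]] <<- if (is.null(cur)) g else cur + g
  }
  input_grads <- list()

  for (i in seq(tp$n, 1L)) {
    g <- grads[[i]]
    if (is.null(g)) next
    nd <- tp$nodes[[i]]
    ins <- nd$inputs
    switch(nd$op,
      input = { input_grads[[as.character(i)]] <- g },
      conv = {
        l <- net$layers[[nd$layer]]
        dx <- nd$cache$dimx
        grads <- accum(grads, ins[1],
          .conv2d_bwd_input(g, l$w, l$stride, l$pad, l$dil, dx[1], dx[2]))
        pr <- .conv2d_bwd_params(node_value(tp, ins[1]), g,
                                 dim(l$w)[1], l$stride, l$pad, l$dil)
        add_pg(nd$layer, "w", pr$gw); add_pg(nd$layer, "b", pr$gb)
      },
      convT = {
        l <- net$layers[[nd$layer]]
        zb <- numeric(dim(l$w)[4])
        grads <- accum(grads, ins[1],
          .conv2d_fwd(g, l$w, zb, l$stride, l$pad, 1L))
        pr <- .conv2d_bwd_params(g, node_value(tp, ins[1]),
                                 dim(l$w)[1], l$stride, l$pad, 1L)
        add_pg(nd$layer, "w", pr$gw)
        d <- dim(g)
        gb <- colSums(matrix(aperm(g, c(1, 2, 4, 3)), ncol = d[3]))
        add_pg(nd$layer, "b", gb)
      },
      bn = {
        l <- net$layers[[nd$layer]]
        cc <- nd$cache; d <- cc$d
        gp <- matrix(aperm(g, c(1, 2, 4, 3)), ncol = d[3])
        m <- nrow(gp)
        add_pg(nd$layer, "beta", colSums(gp))
        add_pg(nd$layer, "gamma", colSums(gp * cc$xh))
        gxh <- gp * matrix(l$gamma, m, d[3], byrow = TRUE)
        if (tp$train) {
          s1 <- colSums(gxh); s2 <- colSums(gxh * cc$xh)
          gxp <- (gxh - matrix(s1 / m, m, d[3], byrow = TRUE) -
                    cc$xh * matrix(s2 / m, m, d[3], byrow = TRUE)) *
            matrix(cc$istd, m, d[3], byrow = TRUE)
        } else {
          gxp <- gxh * matrix(cc$istd, m, d[3], byrow = TRUE)
        }
        grads <- accum(grads, ins[1],
          aperm(array(gxp, d[c(1, 2, 4, 3)]), c(1, 2, 4, 3)))
      },
      dense = {
        l <- net$layers[[nd$layer]]
        add_pg(nd$layer, "w", g %*% t(nd$cache$x))
        grads <- accum(grads, ins[1], t(l$w) %*% g)
      },
      relu = {
        gi <- g; gi[!nd$cache$mask] <- 0
        grads <- accum(grads, ins[1], gi)
      },
      lrelu = {
        gi <- ifelse(nd$cache$mask, g, nd$cache$alpha * g)
        dim(gi) <- dim(g)
        grads <- accum(grads, ins[1], gi)
      },
      sigmoid = {
        y <- nd$value
        grads <- accum(grads, ins[1], g * y * (1 - y))
      },
      pool = {
        grads <- accum(grads, ins[1],
          .maxpool2_bwd(g, nd$cache$idx, nd$cache$H, nd$cache$W))
      },
      unpool = {
        grads <- accum(grads, ins[1],
          .maxunpool2_bwd(g, nd$cache$idx, nd$cache$Ho, nd$cache$Wo))
      },
      axpy = {
        grads <- accum(grads, ins[1], nd$cache$ca * g)
        grads <- accum(grads, ins[2], nd$cache$cb * g)
      },
      gp_avg = {
        d <- nd$cache$d
        grads <- accum(grads, ins[1],
          array(rep(as.vector(g) / (d[1] * d[2]), each = d[1] * d[2]), dim = d))
      },
      gp_max = {
        d <- nd$cache$d
        gx <- array(0, dim = d)
        gxm <- matrix(gx, d[1] * d[2])
        gxm[cbind(nd$cache$am, seq_along(nd$cache$am))] <- as.vector(g)
        grads <- accum(grads, ins[1], array(gxm, dim = d))
      },
      scale_channel = {
        d <- nd$cache$d
        gmat <- node_value(tp, ins[2])
        gb <- array(rep(as.vector(gmat), each = d[1] * d[2]), dim = d)
        grads <- accum(grads, ins[1], g * gb)
        x <- node_value(tp, ins[1])
        gg <- matrix(colSums(matrix(g * x, d[1] * d[2])), d[3], d[4])
        grads <- accum(grads, ins[2], gg)
      },
      ch_avgmap = {
        d <- nd$cache$d
        grads <- accum(grads, ins[1], g[, , rep(1, d[3]), , drop = FALSE] / d[3])
      },
      ch_maxmap = {
        d <- nd$cache$d; am <- nd$cache$am
        gx <- array(0, dim = c(d[1] * d[2], d[3], d[4]))
        gm <- matrix(g, d[1] * d[2], d[4])
        for (n in seq_len(d[4]))
          gx[cbind(seq_len(d[1] * d[2]), am[, n], n)] <- gm[, n]
        grads <- accum(grads, ins[1], array(gx, dim = d))
      },
      concat_ch = {
        ca <- nd$cache$ca; cb <- nd$cache$cb
        grads <- accum(grads, ins[1], g[, , seq_len(ca), , drop = FALSE])
        grads <- accum(grads, ins[2], g[, , ca + seq_len(cb), , drop = FALSE])
      },
      scale_spatial = {
        d <- nd$cache$d
        gmap <- node_value(tp, ins[2])          # (H, W, 1, N)
        gb <- gmap[, , rep(1, d[3]), , drop = FALSE]
        grads <- accum(grads, ins[1], g * gb)
        x <- node_value(tp, ins[1])
        gx <- g * x
        gg <- array(0, dim = c(d[1], d[2], 1, d[4]))
        for (c in seq_len(d[3]))
          gg <- gg + gx[, , c, , drop = FALSE]
        grads <- accum(grads, ins[2], gg)
      },
      stop("unknown op in backward: ", nd$op)
    )
    grads[i] <- list(NULL)  # free memory as we go
  }
  list(param_grads = pg, input_grads = input_grads)
}
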