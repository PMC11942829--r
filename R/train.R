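#' Training engine for the denoising networks
#'
#' Networks are trained on paired low-count (input) / full-count
#' (reference) summed images with a mean-squared-error objective, using
#' Adam or plain SGD. The adversarial model additionally alternates
#' generator and discriminator updates, with the generator objective
#' `MSE + lambda * adversarial`.
#'
#' @name training_engine
NULL

#' Training configuration
#'
#' The published tuning grid restricts batch size to \{4, 16, 32\} and the
#' learning rate to \{1e-3, 1e-4, 1e-5\}; pass `allow_any = TRUE` to use
#' values outside the grid.
#'
#' @param batch_size Images per gradient step.
#' @param learning_rate Step size.
#' @param optimizer `"adam"` or `"sgd"`.
#' @param epochs Training epochs (the study's full-scale setting is 1000;
#'   scale down for desk experiments).
#' @param seed Integer seed controlling initialization and shuffling.
#' @param adv_lambda Weight of the adversarial term for the attngan.
#' @param allow_any Allow values outside the printed grid.
#' @return A `training_config` list.
#' @export
training_config <- function(batch_size = 16L, learning_rate = 1e-3,
                            optimizer = c("adam", "sgd"), epochs = 1000L,
                            seed = 1L, adv_lambda = 0.01, allow_any = FALSE) {
  optimizer <- match.arg(optimizer)
  if (!allow_any) {
    if (!batch_size %in% c(4L, 16L, 32L))
      stop("batch_size must be 4, 16 or 32 (or set allow_any = TRUE)")
    if (!isTRUE(any(abs(learning_rate - c(1e-3, 1e-4, 1e-5)) <
                    1e-12 * learning_rate + 1e-18)))
      stop("learning_rate must be 1e-3, 1e-4 or 1e-5 (or set allow_any = TRUE)")
  }
  stopifnot(epochs >= 1, learning_rate > 0, batch_size >= 1)
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, optimizer = optimizer,
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 adv_lambda = adv_lambda, loss = "mse"),
            class = "training_config")
}

#' Mean-squared-error loss
#'
#' @param prediction,target Numeric arrays of identical shape.
#' @return Mean of squared pixel differences (non-negative scalar).
#' @export
mse_loss <- function(prediction, target) {
  if (!identical(dim(prediction), dim(target)) ||
      length(prediction) != length(target))
    stop("prediction and target shapes differ")
  mean((prediction - target)^2)
}

#' Pixel-wise relative error between two images
#'
#' Mean over pixels of `|a - b| / max(a, b)`, in percent; pixels where
#' both values are zero contribute zero. If both images are entirely
#' zero, returns 0 with a warning.
#'
#' @param candidate,reference Numeric arrays of identical shape.
#' @return Relative error in percent.
#' @export
relative_error <- function(candidate, reference) {
  if (!identical(dim(candidate), dim(reference)) ||
      length(candidate) != length(reference))
    stop("candidate and reference shapes differ")
  hi <- pmax(candidate, reference)
  num <- abs(candidate - reference)
  if (all(hi == 0)) {
    warning("both images are all-zero; relative error defined as 0")
    return(0)
  }
  v <- ifelse(hi == 0, 0, num / hi)
  100 * mean(v)
}

# ---- optimizer --------------------------------------------------------

new_opt_state <- function() new.env(parent = emptyenv())

opt_step <- function(net, grads, cfg, st, scale = 1) {
  if (is.null(st$t)) { st$t <- 0L; st$m <- list(); st$v <- list() }
  st$t <- st$t + 1L
  lr <- cfg$learning_rate
  for (lname in names(grads)) {
    for (field in names(grads[[lname]])) {
      g <- grads[[lname]][[field]] * scale
      key <- paste0(lname, ".", field)
      if (cfg$optimizer == "adam") {
        b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
        m <- if (is.null(st$m[[key]])) g * 0 else st$m[[key]]
        v <- if (is.null(st$v[[key]])) g * 0 else st$v[[key]]
        m <- b1 * m + (1 - b1) * g
        v <- b2 * v + (1 - b2) * g * g
        st$m[[key]] <- m; st$v[[key]] <- v
        mh <- m / (1 - b1^st$t); vh <- v / (1 - b2^st$t)
        upd <- lr * mh / (sqrt(vh) + eps)
      } else {
        mom <- 0.9
        m <- if (is.null(st$m[[key]])) g * 0 else st$m[[key]]
        m <- mom * m + g
        st$m[[key]] <- m
        upd <- lr * m
      }
      net$layers[[lname]][[field]] <- net$layers[[lname]][[field]] - upd
    }
  }
  invisible(net)
}

# ---- data assembly ----------------------------------------------------

pairs_to_arrays <- function(pairs, target_size, channels = 1L) {
  n <- length(pairs)
  x <- array(0, dim = c(target_size, target_size, channels, n))
  y <- array(0, dim = c(target_size, target_size, channels, n))
  for (i in seq_len(n)) {
    xi <- preprocess(pairs[[i]]$input_image, target_size)
    yi <- preprocess(pairs[[i]]$reference_image, target_size)
    for (c in seq_len(channels)) {   # replicated channels in 3-channel mode
      x[, , c, i] <- xi
      y[, , c, i] <- yi
    }
  }
  list(x = x, y = y)
}

eval_mse <- function(net, x, y, chunk = 8L) {
  p <- net_predict(net, x, chunk = chunk)
  mse_loss(p, y)
}

# Numerically stable binary cross-entropy with logits; target t in {0,1}.
bce_logits <- function(z, t) {
  mean(pmax(z, 0) - z * t + log1p(exp(-abs(z))))
}

bce_logits_grad <- function(z, t) {
  (1 / (1 + exp(-z)) - t) / length(z)
}

#' Fit a denoising network to paired images
#'
#' The main model-fitting entry point. Takes paired samples (as built by
#' [build_dataset()] and [split_dataset()]), preprocesses them (resize and
#' \[0, 1\] normalization), trains the requested architecture with MSE
#' loss, and returns a fitted-model object with the usual methods
#' (`print`, `summary`, `predict`, `plot`, `residuals`, `coef`).
#'
#' The recorded loss history holds eval-mode MSE on the training and
#' validation splits at the end of every epoch; epoch 0 is the
#' pre-training loss of the untrained network, so all entries are
#' directly comparable.
#'
#' @param pairs List of `paired_sample` objects with `$split` assigned
#'   (`"train"`/`"val"`/`"test"`); an unsplit list is trained on entirely,
#'   with validation on the training images.
#' @param family Architecture family; see [network_config()].
#' @param config A [training_config()].
#' @param net_config A [network_config()]; defaults to the family default.
#' @param target_size Network input side in pixels.
#' @param verbose Print per-epoch losses every `verbose` epochs (0 = quiet).
#' @param init_net Optional `denoiser_net` to warm-start from (e.g. the
#'   `$net` of an earlier fit); it is copied, never modified in place.
#' @return An object of class `denoiser_fit`.
#' @export
fit_denoiser <- function(pairs, family = c("udncnn", "dncnn", "dudncnn", "attngan"),
                         config = training_config(), net_config = NULL,
                         target_size = 128L, verbose = 0L, init_net = NULL) {
  family <- match.arg(family)
  if (is.null(net_config)) net_config <- network_config(family)
  if (net_config$family != family) stop("net_config family mismatch")
  splits <- vapply(pairs, function(p) {
    s <- p$split
    if (is.null(s) || is.na(s)) "train" else s
  }, character(1))
  tr <- pairs[splits == "train"]
  va <- pairs[splits == "val"]
  if (length(tr) == 0) stop("no training pairs")
  if (length(va) == 0) va <- tr
  ch <- net_config$in_channels
  dtr <- pairs_to_arrays(tr, target_size, ch)
  dva <- pairs_to_arrays(va, target_size, ch)

  net <- if (is.null(init_net)) {
    build_denoiser(net_config, seed = config$seed)
  } else {
    if (!inherits(init_net, "denoiser_net") || init_net$family != family)
      stop("init_net must be a denoiser_net of the same family")
    clone_net(init_net)
  }
  disc <- NULL
  if (family == "attngan")
    disc <- build_pixel_discriminator(net_config, seed = config$seed)

  st <- new_opt_state()
  st_d <- new_opt_state()
  ntr <- length(tr)
  hist <- data.frame(epoch = 0:config$epochs,
                     train_loss = NA_real_, val_loss = NA_real_)
  hist$train_loss[1] <- eval_mse(net, dtr$x, dtr$y)
  hist$val_loss[1] <- eval_mse(net, dva$x, dva$y)

  with_seed(config$seed + 1000L, {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(ntr)
      for (s in seq(1, ntr, by = config$batch_size)) {
        idx <- ord[s:min(s + config$batch_size - 1, ntr)]
        xb <- dtr$x[, , , idx, drop = FALSE]
        yb <- dtr$y[, , , idx, drop = FALSE]
        fw <- net_forward(net, xb, train = TRUE)
        pred <- node_value(fw$tape, fw$out_id)
        loss <- mse_loss(pred, yb)
        if (!is.finite(loss))
          stop("training diverged: non-finite loss at epoch ", ep)
        gseed <- 2 * (pred - yb) / length(pred)
        if (family == "attngan") {
          # generator adversarial term: push D(pred) towards "real"
          fd <- net_forward(disc, pred, train = TRUE)
          z <- node_value(fd$tape, fd$out_id)
          gz <- bce_logits_grad(z, 1)
          bd <- tape_backward(fd$tape, disc, fd$out_id, gz)
          g_adv <- bd$input_grads[[as.character(fd$x_id)]]
          gseed <- gseed + config$adv_lambda * g_adv
        }
        bw <- tape_backward(fw$tape, net, fw$out_id, gseed)
        opt_step(net, bw$param_grads, config, st)
        if (family == "attngan") {
          # discriminator update on real and generated batches
          fr <- net_forward(disc, yb, train = TRUE)
          zr <- node_value(fr$tape, fr$out_id)
          br <- tape_backward(fr$tape, disc, fr$out_id,
                              bce_logits_grad(zr, 1))
          opt_step(disc, br$param_grads, config, st_d, scale = 0.5)
          ff <- net_forward(disc, pred, train = TRUE)
          zf <- node_value(ff$tape, ff$out_id)
          bf <- tape_backward(ff$tape, disc, ff$out_id,
                              bce_logits_grad(zf, 0))
          opt_step(disc, bf$param_grads, config, st_d, scale = 0.5)
        }
      }
      # eval-mode losses at epoch end, so every history entry (including
      # epoch 0) is computed the same way and entries are comparable
      hist$train_loss[ep + 1] <- eval_mse(net, dtr$x, dtr$y)
      hist$val_loss[ep + 1] <- eval_mse(net, dva$x, dva$y)
      if (verbose > 0 && ep %% verbose == 0)
        message(sprintf("epoch %d: train %.3e val %.3e",
                        ep, hist$train_loss[ep + 1], hist$val_loss[ep + 1]))
    }
  })

  fit <- list(net = net, discriminator = disc, family = family,
              config = config, net_config = net_config,
              history = hist, target_size = as.integer(target_size),
              n_train = length(tr), n_val = length(va),
              call = match.call())
  class(fit) <- "denoiser_fit"
  fit
}

#' @export
print.denoiser_fit <- function(x, ...) {
  cat(sprintf("Denoiser fit: %s, %d epochs, batch %d, lr %g (%s)\n",
              x$family, x$config$epochs, x$config$batch_size,
              x$config$learning_rate, x$config$optimizer))
  cat(sprintf("  final train MSE %.4g, val MSE %.4g (epoch-0: %.4g / %.4g)\n",
              utils::tail(x$history$train_loss, 1),
              utils::tail(x$history$val_loss, 1),
              x$history$train_loss[1], x$history$val_loss[1]))
  invisible(x)
}

#' @export
summary.denoiser_fit <- function(object, ...) {
  h <- object$history
  out <- list(
    family = object$family,
    parameters = n_parameters(object$net),
    epochs = object$config$epochs,
    initial = c(train = h$train_loss[1], val = h$val_loss[1]),
    final = c(train = utils::tail(h$train_loss, 1),
              val = utils::tail(h$val_loss, 1)),
    improvement = 1 - utils::tail(h$train_loss, 1) / h$train_loss[1],
    n_train = object$n_train, n_val = object$n_val)
  class(out) <- "summary.denoiser_fit"
  out
}

#' @export
print.summary.denoiser_fit <- function(x, ...) {
  cat(sprintf("%s denoiser: %s parameters, trained %d epochs on %d pairs\n",
              x$family, format(x$parameters, big.mark = ","), x$epochs,
              x$n_train))
  cat(sprintf("  train MSE %.4g -> %.4g (%.1f%% reduction); val MSE %.4g -> %.4g\n",
              x$initial["train"], x$final["train"], 100 * x$improvement,
              x$initial["val"], x$final["val"]))
  invisible(x)
}

#' Denoise images with a fitted model
#'
#' @param object A `denoiser_fit`.
#' @param newdata A matrix (single image), a `(H, W, C, N)` array, a
#'   `summed_image`, or a list of `paired_sample`/`summed_image` objects.
#'   Images are preprocessed exactly as in training.
#' @param ... Unused.
#' @return Denoised image(s), matching the input form (matrices for
#'   matrix/`summed_image`/list input).
#' @export
predict.denoiser_fit <- function(object, newdata, ...) {
  ts <- object$target_size
  ch <- object$net_config$in_channels
  as_input <- function(img) {
    m <- preprocess(img, ts)
    a <- array(0, dim = c(ts, ts, ch, 1))
    for (c in seq_len(ch)) a[, , c, 1] <- m
    a
  }
  if (is.list(newdata) && !inherits(newdata, "summed_image")) {
    return(lapply(newdata, function(p) {
      img <- if (inherits(p, "paired_sample")) p$input_image else p
      predict(object, img)
    }))
  }
  if (is.matrix(newdata) || inherits(newdata, "summed_image")) {
    y <- net_predict(object$net, as_input(newdata))
    # average replicated channels back to one plane
    return(apply(y[, , , 1, drop = FALSE], c(1, 2), mean))
  }
  net_predict(object$net, newdata)
}

#' @export
residuals.denoiser_fit <- function(object, pairs, ...) {
  if (missing(pairs)) stop("supply the paired samples to compute residuals on")
  lapply(pairs, function(p) {
    predict(object, p$input_image) - preprocess(p$reference_image, object$target_size)
  })
}

#' @export
coef.denoiser_fit <- function(object, ...) object$net$layers

#' @export
plot.denoiser_fit <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("black", "red3"), xlab = "epoch",
                    ylab = "MSE loss", main = paste(x$family, "training"), ...)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("black", "red3"), bty = "n")
  invisible(x)
}

#' Grid search over training configurations
#'
#' Trains one model per grid row and ranks configurations by the mean
#' image-level relative error between denoised and reference
#' images on the scoring split (ascending; smaller is better).
#'
#' @param family Architecture family.
#' @param pairs Paired samples with splits assigned.
#' @param grid Data frame with columns `batch_size`, `learning_rate`,
#'   `optimizer`.
#' @param epochs,target_size,seed Training settings shared across rows.
#' @param score_split Split used for scoring (default `"test"`).
#' @param net_config Optional [network_config()].
#' @return The grid with a `score` column, ordered best first; fitted
#'   models in attribute `"fits"`.
#' @export
hyperparameter_search <- function(family, pairs, grid, epochs = 50L,
                                  target_size = 64L, seed = 1L,
                                  score_split = "test", net_config = NULL) {
  if (nrow(grid) < 1) stop("empty grid")
  sc <- pairs[vapply(pairs, function(p) identical(p$split, score_split),
                     logical(1))]
  if (length(sc) == 0) stop("no pairs in scoring split '", score_split, "'")
  scores <- numeric(nrow(grid))
  fits <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cfg <- training_config(batch_size = grid$batch_size[i],
                           learning_rate = grid$learning_rate[i],
                           optimizer = as.character(grid$optimizer[i]),
                           epochs = epochs, seed = seed, allow_any = TRUE)
    # a diverging config scores Inf instead of aborting the search
    fit <- tryCatch(
      fit_denoiser(pairs, family, cfg, net_config = net_config,
                   target_size = target_size),
      error = function(e) NULL)
    if (is.null(fit)) {
      scores[i] <- Inf
      next
    }
    err <- vapply(sc, function(p) {
      pred <- predict(fit, p$input_image)
      if (!all(is.finite(pred))) return(Inf)
      relative_error(pred, preprocess(p$reference_image, target_size))
    }, numeric(1))
    scores[i] <- mean(err)
    fits[[i]] <- fit
  }
  out <- grid
  out$grid_row <- seq_len(nrow(grid))
  out$score <- scores
  ord <- order(scores)
  out <- out[ord, , drop = FALSE]
  attr(out, "fits") <- fits[ord]
  out
}
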