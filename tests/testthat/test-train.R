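test_that("training_config enforces the published hyperparameter grid", {
  ok <- training_config(batch_size = 16, learning_rate = 1e-3)
  expect_identical(ok$batch_size, 16L)
  expect_error(training_config(batch_size = 7), "grid|batch")
  expect_error(training_config(learning_rate = 0.5), "grid|learning")
  expect_error(training_config(optimizer = "rmsprop"))
  # off-grid values allowed only with the explicit override
  loose <- training_config(batch_size = 7, learning_rate = 0.5,
                           allow_any = TRUE)
  expect_identical(loose$batch_size, 7L)
})

test_that("the loss history has epochs + 1 entries anchored at the pre-training loss", {
  pairs <- small_pairs(n = 4, seed = 900)
  tc <- training_config(batch_size = 4, learning_rate = 1e-4, epochs = 3,
                        seed = 5, allow_any = TRUE)
  cfg <- network_config("dncnn", filters = 4)
  fit <- fit_denoiser(pairs, "dncnn", tc, net_config = cfg, target_size = 16L)
  expect_identical(nrow(fit$history), 4L)
  expect_identical(fit$history$epoch, 0:3)
  expect_true(all(fit$history$train_loss >= 0))
  expect_true(all(fit$history$val_loss >= 0))

  # epoch 0 equals the eval-mode loss of the freshly built network
  net0 <- build_denoiser(cfg, seed = tc$seed)
  tr <- pairs[vapply(pairs, function(p) p$split == "train", logical(1))]
  d <- rn$pairs_to_arrays(tr, 16L, 1L)
  expect_equal(fit$history$train_loss[1], rn$eval_mse(net0, d$x, d$y),
               tolerance = 1e-7)
})

test_that("training is deterministic given the seed", {
  pairs <- small_pairs(n = 4, seed = 910)
  tc <- training_config(batch_size = 4, learning_rate = 1e-4, epochs = 3,
                        seed = 9, allow_any = TRUE)
  cfg <- network_config("udncnn", filters = 4)
  f1 <- fit_denoiser(pairs, "udncnn", tc, net_config = cfg, target_size = 16L)
  f2 <- fit_denoiser(pairs, "udncnn", tc, net_config = cfg, target_size = 16L)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$net$layers, f2$net$layers)
})

test_that("a short run reduces training MSE below its pre-training value", {
  pairs <- small_pairs(n = 8, seed = 920, split = c(0.75, 0.125, 0.125))
  tc <- training_config(batch_size = 4, learning_rate = 1e-3, epochs = 10,
                        seed = 2, allow_any = TRUE)
  fit <- fit_denoiser(pairs, "dncnn", tc,
                      net_config = network_config("dncnn", filters = 8),
                      target_size = 32L)
  expect_lt(tail(fit$history$train_loss, 1), fit$history$train_loss[1])
  expect_lt(tail(fit$history$val_loss, 1), fit$history$val_loss[1])
})

test_that("gradient descent drives a noiseless identity task below 1e-4", {
  # target = input: a realizable task that gradient descent must solve
  set.seed(30)
  imgs <- lapply(1:4, function(i) matrix(runif(16 * 16), 16, 16))
  pairs <- lapply(seq_along(imgs), function(i) {
    list(study_id = sprintf("id%d", i), patient_age_years = 5,
         input_image = imgs[[i]], reference_image = imgs[[i]],
         rois = NULL, split = "train")
  })
  tc <- training_config(batch_size = 4, learning_rate = 1e-3, epochs = 600,
                        seed = 3, allow_any = TRUE)
  fit <- fit_denoiser(pairs, "dncnn", tc,
                      net_config = network_config("dncnn", filters = 8),
                      target_size = 16L)
  expect_lt(min(fit$history$train_loss), 1e-4)
  # the loss trend is decreasing: final loss far below the initial one
  expect_lt(tail(fit$history$train_loss, 1), fit$history$train_loss[1] / 10)
})

test_that("training aborts with diagnostics on divergence", {
  pairs <- small_pairs(n = 4, seed = 930)
  tc <- training_config(batch_size = 4, learning_rate = 1e6, epochs = 50,
                        seed = 1, optimizer = "sgd", allow_any = TRUE)
  expect_error(
    fit_denoiser(pairs, "dncnn", tc,
                 net_config = network_config("dncnn", filters = 4),
                 target_size = 16L),
    "diverged|non-finite")
})

test_that("warm starts resume from the given network without touching it", {
  pairs <- small_pairs(n = 4, seed = 940)
  cfg <- network_config("dncnn", filters = 4)
  tc <- training_config(batch_size = 4, learning_rate = 1e-4, epochs = 2,
                        seed = 4, allow_any = TRUE)
  f1 <- fit_denoiser(pairs, "dncnn", tc, net_config = cfg, target_size = 16L)
  w_before <- f1$net$layers$conv1$w
  f2 <- fit_denoiser(pairs, "dncnn", tc, net_config = cfg, target_size = 16L,
                     init_net = f1$net)
  expect_identical(f1$net$layers$conv1$w, w_before)
  # epoch-0 loss of the resumed fit equals the first fit's final state
  tr <- pairs[vapply(pairs, function(p) p$split == "train", logical(1))]
  d <- rn$pairs_to_arrays(tr, 16L, 1L)
  expect_equal(f2$history$train_loss[1], rn$eval_mse(f1$net, d$x, d$y),
               tolerance = 1e-7)
  expect_error(fit_denoiser(pairs, "udncnn", tc,
                            net_config = network_config("udncnn", filters = 4),
                            target_size = 16L, init_net = f1$net),
               "family")
})

test_that("the AttnGAN branch trains generator and discriminator jointly", {
  pairs <- small_pairs(n = 4, seed = 950)
  tc <- training_config(batch_size = 4, learning_rate = 1e-4, epochs = 2,
                        seed = 6, allow_any = TRUE)
  cfg <- network_config("attngan", filters = 4)
  fit <- fit_denoiser(pairs, "attngan", tc, net_config = cfg,
                      target_size = 32L)
  expect_false(is.null(fit$discriminator))
  disc0 <- build_pixel_discriminator(cfg, seed = tc$seed)
  expect_false(is.null(fit$discriminator$layers$d1$w))
  expect_false(identical(fit$discriminator$layers$d1$w,
                         disc0$layers$d1$w))
  expect_true(all(is.finite(fit$history$train_loss)))
})

test_that("denoiser_fit carries the standard modelling methods", {
  pairs <- small_pairs(n = 4, seed = 960)
  tc <- training_config(batch_size = 4, learning_rate = 1e-4, epochs = 2,
                        seed = 8, allow_any = TRUE)
  fit <- fit_denoiser(pairs, "dncnn", tc,
                      net_config = network_config("dncnn", filters = 4),
                      target_size = 16L)
  expect_s3_class(fit, "denoiser_fit")
  expect_output(print(fit), "Denoiser fit")
  sm <- summary(fit)
  expect_s3_class(sm, "summary.denoiser_fit")
  expect_output(print(sm), "dncnn")
  expect_type(coef(fit), "list")
  expect_true("conv1" %in% names(coef(fit)))

  test <- pairs[vapply(pairs, function(p) p$split == "test", logical(1))]
  if (length(test) == 0) test <- pairs[1]
  preds <- predict(fit, test)
  expect_length(preds, length(test))
  expect_identical(dim(preds[[1]]), c(16L, 16L))
  r <- residuals(fit, test)
  expect_equal(preds[[1]] - preprocess(test[[1]]$reference_image, 16L),
               r[[1]], tolerance = 1e-10)
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("hyperparameter_search ranks configs and flags a crippled one last", {
  pairs <- small_pairs(n = 4, seed = 970)
  # singleton grid returns that config ranked first
  g1 <- data.frame(batch_size = 4, learning_rate = 1e-4, optimizer = "adam")
  r1 <- hyperparameter_search("dncnn", pairs, g1, epochs = 2,
                              target_size = 16L, seed = 1)
  expect_identical(nrow(r1), 1L)

  grid <- data.frame(batch_size = c(4, 4), learning_rate = c(1e-4, 1e3),
                     optimizer = "sgd")
  r <- hyperparameter_search("dncnn", pairs, grid, epochs = 2,
                             target_size = 16L, seed = 1)
  expect_identical(sort(r$grid_row), 1:2)          # a permutation
  expect_identical(r$grid_row[nrow(r)], 2L)        # LR 1e3 ranks last
  # rerun with the same seed reproduces the ranking
  r2 <- hyperparameter_search("dncnn", pairs, grid, epochs = 2,
                              target_size = 16L, seed = 1)
  expect_identical(r$grid_row, r2$grid_row)
})
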