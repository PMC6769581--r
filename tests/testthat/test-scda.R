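test_that("conv1d_same handles identity, constant and degenerate cases", {
  set.seed(1)
  inp <- matrix(rnorm(14), 7, 2)
  # delta filter at the center copies the matching input channel
  delta <- array(0, dim = c(3, 2, 2))
  delta[2, 1, 1] <- 1; delta[2, 2, 2] <- 1
  expect_equal(conv1d_same(inp, delta), inp)
  # all-zero filters give sigma(bias) everywhere
  zf <- array(0, dim = c(5, 2, 3))
  out <- conv1d_same(inp, zf, biases = c(-1, 0, 2),
                     activation = function(z) pmax(z, 0))
  expect_equal(out, matrix(rep(c(0, 0, 2), each = 7), 7, 3))
  expect_error(conv1d_same(inp, array(0, dim = c(4, 2, 1))), "odd")
})

test_that("conv1d_same matches the brute-force convolution", {
  set.seed(2)
  for (trial in 1:20) {
    L <- sample(1:12, 1); D <- sample(1:3, 1)
    n <- sample(1:4, 1); k <- sample(c(3, 5, 7), 1)
    inp <- matrix(rnorm(L * D), L, D)
    F <- array(rnorm(k * D * n), c(k, D, n)); b <- rnorm(n)
    expect_lt(max(abs(conv1d_same(inp, F, b) - conv_brute(inp, F, b))),
              1e-10)
  }
})

test_that("the L1 penalty sums absolute filter weights", {
  mod <- build_scda(scda_config(kernel_counts = c(4, 4, 4, 4, 4),
                                filter_size = 3), 8, 2, seed = 1)
  for (l in seq_along(mod$layers)) mod$layers[[l]]$W[] <- 0
  expect_equal(l1_penalty(mod), 0)
  mod$layers[[1]]$W[1:3, 1] <- c(1, -2, 3)
  expect_equal(l1_penalty(mod, lambda = 1e-4), 6e-4)
  expect_equal(l1_penalty(mod, lambda = 2e-4), 2 * l1_penalty(mod, 1e-4))
  # biases are excluded
  mod$layers[[2]]$b[] <- 100
  expect_equal(l1_penalty(mod, lambda = 1e-4), 6e-4)
})

test_that("reconstruction loss has its closed-form values", {
  target <- gm_of(matrix(c(1L, 2L, 3L, 2L), 2, 2), n_classes = 3)
  perfect <- one_hot(target)
  expect_equal(reconstruction_loss(perfect, target), 0)
  uniform <- array(1 / 3, dim = c(2, 2, 3))
  expect_equal(reconstruction_loss(uniform, target), log(3), tolerance = 1e-9)
  # two-class entry with p = (0.8, 0.2), true class 1
  t2 <- gm_of(matrix(1L, 1, 1), n_classes = 2)
  p2 <- array(c(0.8, 0.2), dim = c(1, 1, 2))
  expect_equal(reconstruction_loss(p2, t2), -log(0.8))
  # missing targets are excluded from the mean
  t3 <- gm_of(matrix(c(1L, 0L), 1, 2), n_classes = 2)
  p3 <- array(c(0.5, 0.1, 0.5, 0.9), dim = c(1, 2, 2))
  expect_equal(reconstruction_loss(p3, t3), -log(0.5))
})

test_that("model shapes, padding and parameter count follow the layer plan", {
  cfg <- scda_config()
  mod <- build_scda(cfg, n_markers = 64, n_classes = 3, seed = 1)
  # closed-form parameter count: sum(k * in * out + out) over conv layers
  chain <- c(3, 32, 64, 128, 128, 64, 3)
  expect_equal(scda_parameter_count(mod),
               sum(5 * chain[-7] * chain[-1] + chain[-1]))
  # odd input length: padded internally, cropped on output
  mod63 <- build_scda(cfg, n_markers = 63, n_classes = 3, seed = 1)
  gm <- random_gm(3, 63, n_classes = 3, seed = 2)
  res <- scda_impute(mod63, gm)
  expect_equal(dim(res$probabilities), c(3, 63, 3))
  # probability rows sum to 1
  expect_equal(range(apply(res$probabilities, c(1, 2), sum)), c(1, 1),
               tolerance = 1e-6)
  # five-layer variant
  mod5 <- build_scda(scda_config(depth_variant = "five_layer"), 10, 2,
                     seed = 1)
  chain5 <- c(2, 32, 64, 32, 2)
  expect_equal(scda_parameter_count(mod5),
               sum(5 * chain5[-5] * chain5[-1] + chain5[-1]))
  expect_error(build_scda(cfg, n_markers = 3, n_classes = 3), "n_markers")
})

test_that("config validation rejects invalid hyperparameters", {
  expect_error(scda_config(filter_size = 4), "odd")
  expect_error(scda_config(l1_lambda = -1), "l1_lambda")
  expect_error(scda_config(dropout_p = 1), "dropout_p")
  expect_error(scda_config(kernel_counts = c(8, 8)), "kernel counts")
  expect_error(train_config(batch_size = 0), "batch_size")
})

test_that("imputation preserves observed entries and breaks ties low", {
  mod <- build_scda(scda_config(kernel_counts = c(4, 4, 4, 4, 4),
                                filter_size = 3), 12, 2, seed = 3)
  full <- random_gm(4, 12, n_classes = 2, seed = 4)
  res <- scda_impute(mod, full)
  expect_identical(res$completed$values, full$values)
  gm <- full
  gm$values[1, 5] <- 0L
  res <- scda_impute(mod, gm)
  expect_true(res$completed$values[1, 5] %in% 1:2)
  keep <- gm$values > 0L
  expect_identical(res$completed$values[keep], gm$values[keep])
})

test_that("training reduces the loss and autoencodes clean data", {
  bench <- tiny_cross_benchmark(n = 120, m = 64, seed = 21)
  mod <- build_scda(scda_config(), 64, 2, seed = 1)
  mod <- scda_train(mod, bench$splits$train, bench$train_target,
                    bench$splits$val, bench$val_target,
                    train_config(max_epochs = 10, early_stop_patience = 10,
                                 seed = 2))
  h <- mod$history
  expect_lte(h$train_loss[nrow(h)], h$train_loss[1])
  expect_equal(names(h),
               c("train_loss", "penalty", "val_loss",
                 "val_masked_accuracy", "epoch"))
  # autoencoding sanity: clean input = target, no masking
  clean <- bench$train_target
  mod2 <- build_scda(scda_config(dropout_p = 0), 64, 2, seed = 5)
  mod2 <- scda_train(mod2, clean, clean, bench$val_target, bench$val_target,
                     train_config(max_epochs = 15, early_stop_patience = 15,
                                  seed = 6))
  res <- scda_impute(mod2, clean)
  acc <- mean(decode_argmax(res$probabilities) == clean$values)
  expect_gt(acc, 0.99)
})

test_that("the network output length equals the input length", {
  set.seed(11)
  for (L in c(4, 5, sample(6:200, 3))) {
    mod <- build_scda(scda_config(kernel_counts = c(4, 4, 4, 4, 4),
                                  filter_size = 3), L, 2, seed = 1)
    gm <- random_gm(2, L, n_classes = 2, seed = L)
    res <- scda_impute(mod, gm)
    expect_equal(dim(res$probabilities)[2], L)
  }
})

test_that("adding the L1 penalty never lowers the objective", {
  mod <- build_scda(scda_config(kernel_counts = c(4, 4, 4, 4, 4),
                                filter_size = 3), 8, 2, seed = 7)
  expect_gte(l1_penalty(mod, 1e-3), 0)
  expect_gt(l1_penalty(mod, 1e-3), l1_penalty(mod, 0))
})
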