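test_that("the built network matches its architecture description", {
  cfg <- denoiser_config(n_conv_layers = 5, kernel = 7, n_filters = 16,
                         input_shape = c(64, 64), seed = 2)
  m <- build_denoiser(cfg)
  expect_length(m$layers, 5L)
  expect_equal(dim(m$layers[[1]]$conv$W), c(7 * 7 * 1, 16))
  expect_equal(dim(m$layers[[3]]$conv$W), c(7 * 7 * 16, 16))
  expect_equal(dim(m$layers[[5]]$conv$W), c(7 * 7 * 16, 1))
  expect_true(all(m$layers[[5]]$conv$W == 0))

  # closed-form parameter count: first conv k^2*f + f, hidden convs
  # (L-2)*(k^2*f^2 + f), final conv k^2*f + 1, plus (L-1)*(2f + f) for
  # batch-norm scales/shifts and PReLU slopes
  count <- function(L, k, f)
    (k^2 * f + f) + (L - 2) * (k^2 * f^2 + f) + (k^2 * f + 1) +
      (L - 1) * 3 * f
  expect_equal(n_parameters(m), count(5, 7, 16))
  m2 <- build_denoiser(denoiser_config(3, 3, 4, c(8, 8)))
  expect_equal(n_parameters(m2), count(3, 3, 4))

  expect_error(denoiser_config(kernel = 8), "odd")
  expect_error(denoiser_config(n_conv_layers = 1), ">= 2")
  expect_error(denoiser_config(val_fraction = 1.2), "val_fraction")
})

test_that("the untrained network is the identity map", {
  cfg <- denoiser_config(5, 7, 8, c(32, 32), seed = 5)
  m <- build_denoiser(cfg)
  set.seed(6)
  v <- pet_volume(array(abs(rnorm(32 * 32 * 7, 1.2, 0.4)),
                        dim = c(32, 32, 7)), 0.78, 3, "LC")
  out <- denoise_volume(m, v)
  expect_lt(max(abs(out$values - v$values)), 1e-6)
  expect_equal(out$meta, "LC+DL")

  # fully convolutional: other slice sizes pass through too
  v2 <- pet_volume(array(rnorm(20 * 28 * 3), dim = c(20, 28, 3)),
                   0.78, 3, "LC")
  out2 <- denoise_volume(m, v2)
  expect_equal(dim(out2$values), c(20, 28, 3))
  expect_lt(max(abs(out2$values - v2$values)), 1e-6)

  bad <- v
  bad$values[1] <- Inf
  expect_error(denoise_volume(m, bad), "finite")
})

test_that("train/validation split is exact, disjoint and seeded", {
  sp <- split_train_val(seq_len(7080), 0.10, seed = 4)
  expect_length(sp$val, 708L)
  expect_length(sp$train, 6372L)
  expect_length(intersect(sp$train, sp$val), 0L)
  expect_setequal(c(sp$train, sp$val), seq_len(7080))

  sp10 <- split_train_val(as.list(1:10), 0.10, seed = 1)
  expect_length(sp10$val, 1L)
  expect_length(sp10$train, 9L)

  expect_identical(split_train_val(1:100, 0.2, seed = 7),
                   split_train_val(1:100, 0.2, seed = 7))
  expect_error(split_train_val(1:10, 0, seed = 1), "val_fraction")
  expect_error(split_train_val(list(), 0.1, seed = 1), "non-empty")
})

test_that("training reduces the MSE on seeded synthetic pairs", {
  set.seed(21)
  # smooth targets corrupted by noise: the network must learn to denoise
  smooth_field <- function() {
    f <- matrix(rnorm(16 * 16), 16)
    k <- dnorm(-3:3, sd = 1.5); k <- k / sum(k)
    f <- apply(f, 2, function(col) stats::filter(c(rev(col[1:3]), col,
                                                   rev(col[14:16])),
                                                 k)[4:19])
    t(apply(t(f), 2, function(row) stats::filter(c(rev(row[1:3]), row,
                                                   rev(row[14:16])),
                                                 k)[4:19])) + 2
  }
  pairs <- lapply(1:40, function(i) {
    fc <- smooth_field()
    list(lc = fc + matrix(rnorm(256, sd = 0.3), 16), fc = fc)
  })
  cfg <- denoiser_config(n_conv_layers = 3, kernel = 5, n_filters = 8,
                         input_shape = c(16, 16), epochs = 4,
                         batch_size = 8, seed = 3)
  m <- train_denoiser(build_denoiser(cfg), pairs)
  expect_equal(nrow(m$history), 4L)
  expect_true(all(is.finite(m$history$val_mse)))
  # identity init means epoch-0 MSE equals the raw LC-FC gap; training must
  # beat the first epoch by the end
  expect_lt(m$history$train_mse[4], m$history$train_mse[1])
  expect_lt(min(m$history$val_mse), 0.3^2)
  # best-so-far validation MSE is non-increasing by construction
  expect_true(all(diff(cummin(m$history$val_mse)) <= 0))
})

test_that("training with identical LC/FC pairs keeps zero loss at the
           identity initialisation", {
  set.seed(8)
  pairs <- lapply(1:12, function(i) {
    x <- matrix(abs(rnorm(64, 1, 0.2)), 8)
    list(lc = x, fc = x)
  })
  cfg <- denoiser_config(3, 3, 4, c(8, 8), epochs = 2, batch_size = 4,
                         seed = 9)
  m <- train_denoiser(build_denoiser(cfg), pairs)
  expect_lt(m$history$train_mse[1], 1e-12)
  expect_lte(m$history$val_mse[2], m$history$val_mse[1] + 1e-12)
})

test_that("epochs = 0 is a no-op and shape mismatches are rejected", {
  cfg <- denoiser_config(3, 3, 4, c(8, 8), epochs = 0, seed = 1)
  m <- build_denoiser(cfg)
  pairs <- lapply(1:6, function(i) list(lc = matrix(0, 8, 8),
                                        fc = matrix(0, 8, 8)))
  m2 <- train_denoiser(m, pairs)
  expect_identical(m2$layers, m$layers)
  expect_equal(nrow(m2$history), 0L)

  cfg1 <- denoiser_config(3, 3, 4, c(8, 8), epochs = 1, batch_size = 2,
                          seed = 1)
  bad <- list(list(lc = matrix(0, 8, 8), fc = matrix(0, 8, 9)))
  expect_error(train_denoiser(build_denoiser(cfg1), bad), "identical shape")
})

test_that("a saved model round-trips through its directory layout", {
  cfg <- denoiser_config(3, 3, 4, c(8, 8), epochs = 1, batch_size = 4,
                         seed = 14)
  set.seed(15)
  pairs <- lapply(1:10, function(i) {
    x <- matrix(abs(rnorm(64, 1, 0.2)), 8)
    list(lc = x + rnorm(64, sd = 0.1), fc = x)
  })
  m <- train_denoiser(build_denoiser(cfg), pairs)
  dir <- file.path(tempdir(), "dn-model")
  save_denoiser(m, dir)
  expect_true(all(file.exists(file.path(dir, c("config.json", "history.csv",
                                               "weights.rds")))))
  m2 <- load_denoiser(dir)
  v <- pet_volume(array(abs(rnorm(64 * 3, 1, 0.2)), dim = c(8, 8, 3)),
                  0.78, 3, "LC")
  expect_equal(denoise_volume(m2, v)$values, denoise_volume(m, v)$values)
  unlink(dir, recursive = TRUE)
})
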