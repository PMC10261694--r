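#' Denoiser architecture and training configuration
#'
#' The denoiser is a residual convolutional network operating on single 2-d
#' axial slices in raw SUV units: `n_conv_layers` convolutions with odd
#' `kernel` size and "same" zero padding, each of the first
#' `n_conv_layers - 1` followed by batch normalisation and a PReLU
#' activation with `n_filters` channels, then a final 1-channel convolution
#' whose output is added back onto the input (residual learning: the network
#' learns the full-count minus low-count difference). The final convolution
#' is zero-initialised, so an untrained network is exactly the identity map.
#'
#' Defaults mirror a published dbPET denoising network: 5 layers, 15 x 15
#' kernels, 128 filters, Adam at learning rate 0.001, batch size 16,
#' 100 epochs, 10% of slices reserved for validation. The network is fully
#' convolutional, so inference accepts any slice size; `input_shape` is
#' recorded for provenance only.
#'
#' @param n_conv_layers total number of convolutions (>= 2).
#' @param kernel odd convolution kernel side length.
#' @param n_filters channels of the hidden layers.
#' @param input_shape `c(rows, cols)` of the training slices.
#' @param learning_rate Adam learning rate.
#' @param batch_size minibatch size.
#' @param epochs training epochs.
#' @param val_fraction fraction of slices reserved for validation, in (0, 1).
#' @param seed integer seed for weight initialisation, the train/validation
#'   split and batch shuffling.
#' @param bn_momentum exponential-moving-average momentum of the batch-norm
#'   running statistics.
#' @param bn_eps batch-norm variance floor.
#' @return An object of class `denoiser_config`.
#' @export
denoiser_config <- function(n_conv_layers = 5, kernel = 15, n_filters = 128,
                            input_shape = c(236, 132),
                            learning_rate = 0.001, batch_size = 16,
                            epochs = 100, val_fraction = 0.10, seed = 1,
                            bn_momentum = 0.1, bn_eps = 1e-5) {
  if (kernel %% 2 == 0) stop("`kernel` must be odd", call. = FALSE)
  if (n_conv_layers < 2) stop("`n_conv_layers` must be >= 2", call. = FALSE)
  if (val_fraction <= 0 || val_fraction >= 1)
    stop("`val_fraction` must lie in (0, 1)", call. = FALSE)
  structure(list(n_conv_layers = as.integer(n_conv_layers),
                 kernel = as.integer(kernel),
                 n_filters = as.integer(n_filters),
                 input_shape = as.integer(input_shape),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 val_fraction = val_fraction, seed = as.integer(seed),
                 bn_momentum = bn_momentum, bn_eps = bn_eps),
            class = "denoiser_config")
}

#' Build an untrained denoiser
#'
#' Hidden convolutions are He-initialised (seeded); batch-norm scales start
#' at 1 and shifts at 0; PReLU slopes at 0.25 (one per channel); the final
#' convolution is zero-initialised so that the untrained network is the
#' identity map — a testable starting point for residual learning.
#'
#' @param config a [denoiser_config()].
#' @return An object of class `trained_denoiser` with empty training history.
#' @export
build_denoiser <- function(config) {
  stopifnot(inherits(config, "denoiser_config"))
  k <- config$kernel
  L <- config$n_conv_layers
  f <- config$n_filters
  layers <- with_seed(config$seed, {
    out <- vector("list", L)
    c_in <- 1L
    for (l in seq_len(L - 1L)) {
      fan_in <- k * k * c_in
      out[[l]] <- list(
        conv = list(W = matrix(rnorm(fan_in * f, sd = sqrt(2 / fan_in)),
                               fan_in, f),
                    b = rep(0, f)),
        bn = list(gamma = rep(1, f), beta = rep(0, f),
                  running_mean = rep(0, f), running_var = rep(1, f),
                  momentum = config$bn_momentum, eps = config$bn_eps),
        prelu = list(alpha = rep(0.25, f)))
      c_in <- f
    }
    out[[L]] <- list(conv = list(W = matrix(0, k * k * c_in, 1L), b = 0))
    out
  })
  structure(list(config = config, layers = layers,
                 history = data.frame(epoch = integer(0),
                                      train_mse = numeric(0),
                                      val_mse = numeric(0))),
            class = "trained_denoiser")
}

#' Number of trainable parameters
#'
#' Counts convolution weights and biases, batch-norm scales and shifts, and
#' PReLU slopes of a built model.
#'
#' @param model a `trained_denoiser`.
#' @return Integer parameter count.
#' @export
n_parameters <- function(model) {
  stopifnot(inherits(model, "trained_denoiser"))
  total <- 0L
  for (layer in model$layers) {
    total <- total + length(layer$conv$W) + length(layer$conv$b)
    if (!is.null(layer$bn))
      total <- total + length(layer$bn$gamma) + length(layer$bn$beta)
    if (!is.null(layer$prelu)) total <- total + length(layer$prelu$alpha)
  }
  total
}

#' Split slices into training and validation sets
#'
#' Reserves `round(val_fraction * n)` randomly chosen elements for
#' validation; the split is disjoint, exhaustive and fully determined by
#' `seed`.
#'
#' @param slices a list (or vector) of training samples.
#' @param val_fraction fraction reserved for validation, in (0, 1).
#' @param seed integer seed.
#' @return A list with elements `train` and `val`.
#' @export
split_train_val <- function(slices, val_fraction, seed) {
  if (val_fraction <= 0 || val_fraction >= 1)
    stop("`val_fraction` must lie in (0, 1)", call. = FALSE)
  n <- length(slices)
  if (n == 0L) stop("`slices` must be non-empty", call. = FALSE)
  n_val <- round(val_fraction * n)
  idx <- with_seed(seed, sample.int(n, n_val))
  list(train = slices[setdiff(seq_len(n), idx)], val = slices[sort(idx)])
}

# ---- internal network machinery ------------------------------------------

# Forward pass. x4: H x W x 1 x B. Returns prediction (same dims) and,
# when training, the per-layer caches and updated batch-norm state.
nn_forward <- function(model, x4, training = FALSE) {
  L <- model$config$n_conv_layers
  k <- model$config$kernel
  a <- x4
  caches <- if (training) vector("list", L - 1L) else NULL
  for (l in seq_len(L - 1L)) {
    layer <- model$layers[[l]]
    z <- .conv2d_forward(a, layer$conv$W, layer$conv$b, k)
    bn <- layer$bn
    r <- .bn_prelu_forward(z, bn$gamma, bn$beta, layer$prelu$alpha,
                           bn$running_mean, bn$running_var,
                           bn$momentum, bn$eps, training)
    if (training) {
      caches[[l]] <- list(a_in = a, xhat = r$xhat, invstd = r$invstd)
      model$layers[[l]]$bn$running_mean <- r$running_mean
      model$layers[[l]]$bn$running_var <- r$running_var
    }
    a <- r$y
  }
  res <- .conv2d_forward(a, model$layers[[L]]$conv$W,
                         model$layers[[L]]$conv$b, k)
  list(pred = x4 + res, a_last = a, caches = caches, model = model)
}

adam_init <- function(layers) {
  lapply(layers, function(layer) {
    st <- list(conv = list(W = list(m = layer$conv$W * 0,
                                    v = layer$conv$W * 0),
                           b = list(m = layer$conv$b * 0,
                                    v = layer$conv$b * 0)))
    if (!is.null(layer$bn))
      st$bn <- list(gamma = list(m = layer$bn$gamma * 0,
                                 v = layer$bn$gamma * 0),
                    beta = list(m = layer$bn$beta * 0,
                                v = layer$bn$beta * 0))
    if (!is.null(layer$prelu))
      st$prelu <- list(alpha = list(m = layer$prelu$alpha * 0,
                                    v = layer$prelu$alpha * 0))
    st
  })
}

adam_step <- function(param, grad, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^t)
  vhat <- state$v / (1 - beta2^t)
  list(param = param - lr * mhat / (sqrt(vhat) + eps), state = state)
}

# One training step on a batch. lc4/fc4: H x W x 1 x B.
train_batch <- function(model, opt, lc4, fc4, t) {
  cfg <- model$config
  k <- cfg$kernel
  L <- cfg$n_conv_layers
  fwd <- nn_forward(model, lc4, training = TRUE)
  model <- fwd$model
  err <- fwd$pred - fc4
  loss <- mean(err^2)
  g <- 2 * err / length(err)

  grads <- vector("list", L)
  bw <- .conv2d_backward(fwd$a_last, model$layers[[L]]$conv$W, g, k)
  grads[[L]] <- list(conv = list(W = bw$gW, b = bw$gb))
  dy <- bw$gx
  for (l in seq.int(L - 1L, 1L)) {
    layer <- model$layers[[l]]
    cache <- fwd$caches[[l]]
    bb <- .bn_prelu_backward(dy, cache$xhat, cache$invstd,
                             layer$bn$gamma, layer$bn$beta,
                             layer$prelu$alpha)
    cb <- .conv2d_backward(cache$a_in, layer$conv$W, bb$dx, k,
                           need_gx = l > 1L)
    grads[[l]] <- list(conv = list(W = cb$gW, b = cb$gb),
                       bn = list(gamma = bb$dgamma, beta = bb$dbeta),
                       prelu = list(alpha = bb$dalpha))
    dy <- cb$gx
  }

  lr <- cfg$learning_rate
  for (l in seq_len(L)) {
    for (grp in names(grads[[l]])) {
      for (nm in names(grads[[l]][[grp]])) {
        up <- adam_step(model$layers[[l]][[grp]][[nm]],
                        grads[[l]][[grp]][[nm]],
                        opt[[l]][[grp]][[nm]], lr, t)
        model$layers[[l]][[grp]][[nm]] <- up$param
        opt[[l]][[grp]][[nm]] <- up$state
      }
    }
  }
  list(model = model, opt = opt, loss = loss)
}

stack_slices <- function(slices, idx) {
  d <- dim(slices[[idx[1]]])
  array(unlist(slices[idx], use.names = FALSE), dim = c(d[1], d[2], 1L,
                                                        length(idx)))
}

predict_slices <- function(model, slices, idx) {
  bs <- model$config$batch_size
  out <- vector("list", length(idx))
  for (start in seq(1L, length(idx), by = bs)) {
    take <- idx[start:min(start + bs - 1L, length(idx))]
    x4 <- stack_slices(slices, take)
    pred <- nn_forward(model, x4, training = FALSE)$pred
    for (j in seq_along(take))
      out[[start + j - 1L]] <- pred[, , 1L, j]
  }
  out
}

mse_on_pairs <- function(model, lc, fc, idx) {
  if (length(idx) == 0L) return(NA_real_)
  pred <- predict_slices(model, lc, idx)
  num <- 0
  den <- 0
  for (j in seq_along(idx)) {
    e <- pred[[j]] - fc[[idx[j]]]
    num <- num + sum(e^2)
    den <- den + length(e)
  }
  num / den
}

#' Train the denoiser on paired low-count / full-count slices
#'
#' Minimises the mean squared error between the network prediction and the
#' full-count slice with Adam, at the configured learning rate, batch size
#' and epoch count. A fraction of the pairs (`config$val_fraction`) is held
#' out for validation (seeded, slice-level split) unless `val_pairs` is
#' supplied; validation MSE is evaluated each epoch with batch normalisation
#' in inference mode. With `epochs = 0` the model is returned untouched with
#' an empty history.
#'
#' @param model a `trained_denoiser` from [build_denoiser()].
#' @param pairs list of pairs, each a list with matrices `lc` and `fc` of
#'   identical shape.
#' @param config optional [denoiser_config()] overriding `model$config`.
#' @param val_pairs optional held-out pairs; if `NULL`, split internally.
#' @return The fitted `trained_denoiser`, with `history` holding per-epoch
#'   training and validation MSE.
#' @export
train_denoiser <- function(model, pairs, config = NULL, val_pairs = NULL) {
  stopifnot(inherits(model, "trained_denoiser"))
  if (!is.null(config)) model$config <- config
  cfg <- model$config
  if (cfg$epochs == 0L) return(model)
  for (p in pairs)
    if (!identical(dim(p$lc), dim(p$fc)))
      stop("LC/FC slices within a pair must have identical shape",
           call. = FALSE)
  if (length(pairs) < cfg$batch_size)
    stop("need at least `batch_size` training pairs", call. = FALSE)

  if (is.null(val_pairs)) {
    sp <- split_train_val(pairs, cfg$val_fraction, derive_seeds(cfg$seed, 2)[1])
    pairs <- sp$train
    val_pairs <- sp$val
  }
  lc <- lapply(pairs, `[[`, "lc")
  fc <- lapply(pairs, `[[`, "fc")
  lc_val <- lapply(val_pairs, `[[`, "lc")
  fc_val <- lapply(val_pairs, `[[`, "fc")

  opt <- adam_init(model$layers)
  t <- 0L
  history <- vector("list", cfg$epochs)
  with_seed(derive_seeds(cfg$seed, 2)[2], {
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample.int(length(lc))
      tot_loss <- 0
      tot_n <- 0
      for (start in seq(1L, length(ord), by = cfg$batch_size)) {
        take <- ord[start:min(start + cfg$batch_size - 1L, length(ord))]
        lc4 <- stack_slices(lc, take)
        fc4 <- stack_slices(fc, take)
        t <- t + 1L
        step <- train_batch(model, opt, lc4, fc4, t)
        model <- step$model
        opt <- step$opt
        tot_loss <- tot_loss + step$loss * length(take)
        tot_n <- tot_n + length(take)
      }
      history[[epoch]] <- data.frame(
        epoch = epoch, train_mse = tot_loss / tot_n,
        val_mse = mse_on_pairs(model, lc_val, fc_val,
                               seq_along(lc_val)))
    }
  })
  model$history <- do.call(rbind, history)
  if (any(!is.finite(model$history$train_mse)))
    warning("training diverged: non-finite MSE in history", call. = FALSE)
  model
}

#' Apply the denoiser to a volume
#'
#' Runs the network on each axial slice (batch normalisation in inference
#' mode, using the running statistics accumulated during training) and adds
#' the predicted residual to the input. The network is fully convolutional:
#' any slice size is accepted.
#'
#' @param model a `trained_denoiser`.
#' @param vol a [pet_volume()] with finite values.
#' @return A [pet_volume()] tagged `"LC+DL"`.
#' @export
denoise_volume <- function(model, vol) {
  stopifnot(inherits(model, "trained_denoiser"), inherits(vol, "pet_volume"))
  if (!all(is.finite(vol$values)))
    stop("input volume must be finite", call. = FALSE)
  d <- dim(vol$values)
  slices <- lapply(seq_len(d[3]), function(z) vol$values[, , z])
  pred <- predict_slices(model, slices, seq_len(d[3]))
  out <- array(unlist(pred, use.names = FALSE), dim = d)
  pet_volume(out, spacing = vol$spacing, duration_min = vol$duration_min,
             meta = "LC+DL")
}

#' Save / load a trained denoiser
#'
#' The model directory holds `config.json` (architecture and training
#' hyper-parameters), `history.csv` (per-epoch MSE) and `weights.rds`
#' (fitted tensors).
#'
#' @param model a `trained_denoiser`.
#' @param dir directory to create/read.
#' @return `save_denoiser()` returns `dir` invisibly; `load_denoiser()`
#'   returns the model.
#' @export
save_denoiser <- function(model, dir) {
  stopifnot(inherits(model, "trained_denoiser"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass(model$config),
                       file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  write.csv(model$history, file.path(dir, "history.csv"), row.names = FALSE)
  saveRDS(model$layers, file.path(dir, "weights.rds"))
  invisible(dir)
}

#' @rdname save_denoiser
#' @export
load_denoiser <- function(dir) {
  cfg <- jsonlite::read_json(file.path(dir, "config.json"),
                             simplifyVector = TRUE)
  config <- do.call(denoiser_config,
                    cfg[names(cfg) %in% names(formals(denoiser_config))])
  layers <- readRDS(file.path(dir, "weights.rds"))
  history <- utils::read.csv(file.path(dir, "history.csv"))
  structure(list(config = config, layers = layers, history = history),
            class = "trained_denoiser")
}
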