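# Dual-encoder convolutional encoder-decoder: configuration, training loop,
# prediction and the pixel-wise softmax cross-entropy loss.
#
# Each encoder is a truncated VGG-19-style stack: block b holds conv+BN+PReLU
# layers (2 convs for blocks 1-2, 4 for deeper blocks) with channel width
# base_filters * 2^min(b-1, 3), followed by 2x2 max pooling.  The two encoder
# outputs are concatenated channel-wise and reduced by a 1x1 conv back to the
# single-encoder width; the decoder mirrors the encoder with 2x nearest
# upsampling in place of pooling; a final 1x1 conv + softmax yields per-pixel
# class probabilities.

#' Model configuration
#'
#' Defaults follow the reference training protocol (batch 8, 50 epochs, 10
#' steps per epoch, learning rate 1e-5, batch norm on); see [desk_config()]
#' for a small CPU-scale preset.
#'
#' @param input_shape integer `(H, W)`; both must be divisible by
#'   `2^encoder_blocks`.
#' @param num_classes number of classes (default 2: background / IMC).
#' @param encoder_blocks encoder depth, 3-5 (default 4).
#' @param base_filters channel width of the first block (default 64).
#' @param batch_norm use batch normalization (default TRUE).
#' @param learning_rate Adam learning rate (default 1e-5).
#' @param batch_size samples per gradient step (default 8).
#' @param epochs training epochs (default 50).
#' @param steps_per_epoch augmented batches per epoch (default 10).
#' @param seed seed for weight init and batch sampling.
#' @return a `model_config` object.
#' @export
model_config <- function(input_shape = c(64L, 128L), num_classes = 2L,
                         encoder_blocks = 4L, base_filters = 64L,
                         batch_norm = TRUE, learning_rate = 1e-5,
                         batch_size = 8L, epochs = 50L, steps_per_epoch = 10L,
                         seed = 1L) {
  cfg <- structure(list(input_shape = as.integer(input_shape),
                        num_classes = as.integer(num_classes),
                        encoder_blocks = as.integer(encoder_blocks),
                        base_filters = as.integer(base_filters),
                        batch_norm = isTRUE(batch_norm),
                        learning_rate = learning_rate,
                        batch_size = as.integer(batch_size),
                        epochs = as.integer(epochs),
                        steps_per_epoch = as.integer(steps_per_epoch),
                        seed = as.integer(seed)),
                   class = "model_config")
  validate_model_config(cfg)
  cfg
}

validate_model_config <- function(cfg) {
  with(cfg, {
    if (length(input_shape) != 2 || any(input_shape < 8)) stop_cfg("input_shape must be (H, W)")
    if (encoder_blocks < 3 || encoder_blocks > 5) stop_cfg("encoder_blocks must be 3-5")
    if (any(input_shape %% 2^encoder_blocks != 0))
      stop_cfg("input shape %dx%d not divisible by 2^%d", input_shape[1], input_shape[2], encoder_blocks)
    if (num_classes < 2) stop_cfg("num_classes must be >= 2")
    if (base_filters < 1 || batch_size < 1 || epochs < 0 || steps_per_epoch < 1)
      stop_cfg("counts must be positive (epochs may be 0)")
    if (learning_rate <= 0) stop_cfg("learning_rate must be positive")
  })
  invisible(cfg)
}

#' Desk-scale model preset
#'
#' A configuration small enough to train on one CPU in minutes: 64 x 128
#' inputs, 3 encoder blocks, 16 base filters, 15 epochs, Adam at its
#' conventional 1e-3 rate (the full-scale 1e-5 rate is matched to 500
#' full-resolution steps and learns too slowly in a 150-step desk run).
#'
#' @param epochs training epochs (default 15).
#' @param seed RNG seed.
#' @return a `model_config`.
#' @export
desk_config <- function(epochs = 15L, seed = 1L) {
  model_config(input_shape = c(64L, 128L), encoder_blocks = 3L,
               base_filters = 16L, learning_rate = 1e-3, epochs = epochs,
               seed = seed)
}

#' Build a dual-encoder segmentation model
#'
#' Weights are He-initialized from `cfg$seed`; two builds with the same config
#' have identical initial weights.
#'
#' @param cfg a `model_config`.
#' @return an `imc_model` handle.
#' @export
build_model <- function(cfg) {
  validate_model_config(cfg)
  ptr <- net_create(cfg$input_shape[1], cfg$input_shape[2], cfg$num_classes,
                    cfg$encoder_blocks, cfg$base_filters, cfg$batch_norm,
                    cfg$seed)
  structure(list(ptr = ptr, cfg = cfg), class = "imc_model")
}

#' @export
print.imc_model <- function(x, ...) {
  d <- net_describe(x$ptr)
  cat(sprintf("imc_model: %dx%d input, %d blocks, %d base filters, %d conv layers, %s params\n",
              d$H, d$W, d$blocks, d$base_filters, d$n_layers,
              format(d$n_params, big.mark = ",")))
  invisible(x)
}

#' Pixel-wise softmax cross-entropy loss
#'
#' Mean over pixels of the negative log softmax probability of the true
#' class: `(1/N) sum_j sum_i y_ji * (-log softmax(p_j)_i)`. Nonnegative, and
#' equal to `log(k)` for uniform predictions.
#'
#' @param y N x k one-hot label matrix (rows sum to 1).
#' @param p N x k pre-softmax score matrix.
#' @return scalar loss, >= 0.
#' @export
softmax_loss <- function(y, p) {
  y <- as.matrix(y); p <- as.matrix(p)
  if (!identical(dim(y), dim(p))) stop_cfg("y and p shapes differ")
  if (any(abs(rowSums(y) - 1) > 1e-6)) stop_cfg("label rows must sum to 1")
  z <- p - apply(p, 1, max)
  logp <- z - log(rowSums(exp(z)))
  -mean(rowSums(y * logp))
}

samples_to_cubes <- function(batch) {
  h <- nrow(batch[[1]]$pair$sobel); w <- ncol(batch[[1]]$pair$sobel)
  n <- length(batch)
  x1 <- array(0, c(h, w, n)); x2 <- array(0, c(h, w, n)); fg <- array(0, c(h, w, n))
  for (i in seq_len(n)) {
    x1[, , i] <- batch[[i]]$pair$prewitt
    x2[, , i] <- batch[[i]]$pair$sobel
    fg[, , i] <- batch[[i]]$mask
  }
  list(x1 = x1, x2 = x2, fg = fg)
}

#' Train the model on (gradient pair, mask) samples
#'
#' Per epoch, `steps_per_epoch` batches of `batch_size` freshly augmented
#' samples are consumed (so augmentation multiplies the data each epoch);
#' each batch takes one Adam step on the softmax cross-entropy. Fully seeded:
#' the same config and data give an identical history.
#'
#' @param model an `imc_model` from [build_model()].
#' @param train_set list of `list(pair = gradient_pair, mask = 0/1 matrix)`.
#' @param aug an `augment_config`; `NULL` disables augmentation.
#' @return data.frame history with columns `epoch`, `loss` (per-epoch mean).
#' @export
train_model <- function(model, train_set, aug = augment_config()) {
  if (length(train_set) == 0) stop_cfg("empty training set")
  cfg <- model$cfg
  hshape <- dim(train_set[[1]]$pair$sobel)
  if (!identical(as.integer(hshape), cfg$input_shape))
    stop_cfg("training samples are %dx%d but model expects %dx%d",
             hshape[1], hshape[2], cfg$input_shape[1], cfg$input_shape[2])
  history <- data.frame(epoch = integer(0), loss = numeric(0))
  draw <- 0L
  for (epoch in seq_len(cfg$epochs)) {
    losses <- numeric(cfg$steps_per_epoch)
    for (step in seq_len(cfg$steps_per_epoch)) {
      idx <- withr_seed(derive_seed(cfg$seed, 7000L + draw), function()
        sample.int(length(train_set), cfg$batch_size, replace = TRUE))
      batch <- lapply(seq_along(idx), function(j) {
        s <- train_set[[idx[j]]]
        if (is.null(aug)) return(s)
        out <- augment_pair(s$pair, s$mask, aug, draw * cfg$batch_size + j)
        list(pair = out$pair, mask = out$mask)
      })
      cb <- samples_to_cubes(batch)
      losses[step] <- net_train_step(model$ptr, cb$x1, cb$x2, cb$fg, cfg$learning_rate)
      draw <- draw + 1L
    }
    history <- rbind(history, data.frame(epoch = epoch, loss = mean(losses)))
  }
  if (cfg$batch_norm && cfg$epochs > 0) calibrate_bn(model, train_set)
  history
}

# Finalize batch-norm running statistics with forward-only passes over the
# clean (unaugmented) training set.  With exponential averaging at momentum
# 0.9 the running stats reflect activations of *past* weights; after a short
# Adam run at 1e-3 that lag is large enough to wreck inference-mode
# predictions, so the stats are re-estimated under the final weights.
calibrate_bn <- function(model, train_set, sweeps = 10L) {
  bs <- model$cfg$batch_size
  n <- length(train_set)
  starts <- seq(1L, n, by = bs)
  for (sw in seq_len(sweeps)) {
    for (b in starts) {
      idx <- b:min(b + bs - 1L, n)
      cb <- samples_to_cubes(train_set[idx])
      net_calibrate(model$ptr, cb$x1, cb$x2)
    }
  }
  invisible(model)
}

#' Per-pixel class probabilities for one gradient pair
#'
#' @param model an `imc_model`.
#' @param pair a `gradient_pair` shaped like the model input.
#' @return array `(H, W, k)`; probabilities per pixel sum to 1.
#' @export
predict_probs <- function(model, pair) {
  h <- model$cfg$input_shape[1]; w <- model$cfg$input_shape[2]
  if (!identical(as.integer(dim(pair$sobel)), c(h, w)))
    stop_cfg("input is %dx%d but model expects %dx%d",
             nrow(pair$sobel), ncol(pair$sobel), h, w)
  x1 <- array(pair$prewitt, c(h, w, 1))
  x2 <- array(pair$sobel, c(h, w, 1))
  pm <- net_predict(model$ptr, x1, x2)
  array(pm[, , , 1], dim(pm)[1:3])
}

#' Binarize a two-class probability map
#'
#' Per-pixel argmax with ties going to background: foreground iff
#' `p_fg > 0.5`.
#'
#' @param pm array `(H, W, 2)` of class probabilities (class 2 = foreground).
#' @return 0/1 matrix.
#' @export
binarize <- function(pm) {
  if (length(dim(pm)) != 3 || dim(pm)[3] != 2)
    stop_cfg("binarize expects an (H, W, 2) probability map")
  matrix(as.integer(pm[, , 2] > 0.5), dim(pm)[1], dim(pm)[2])
}

#' Predict a refined band mask end-to-end
#'
#' @param model an `imc_model`.
#' @param pair a `gradient_pair`.
#' @param chain morphological chain (default [default_morph_chain()]);
#'   `NULL` skips refinement.
#' @return 0/1 matrix.
#' @export
predict_mask <- function(model, pair, chain = default_morph_chain()) {
  m <- binarize(predict_probs(model, pair))
  if (is.null(chain)) m else refine(m, chain)
}

#' Save model weights and configuration
#' @param model an `imc_model`.
#' @param path output `.rds` path.
#' @export
save_model <- function(model, path) {
  saveRDS(list(cfg = model$cfg, weights = net_weights(model$ptr)), path)
  invisible(path)
}

#' Load a model saved by [save_model()]
#' @param path `.rds` path.
#' @return an `imc_model` (optimizer state is not restored).
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  model <- build_model(obj$cfg)
  net_set_weights(model$ptr, obj$weights)
  model
}
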