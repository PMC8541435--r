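test_that("softmax_loss matches closed forms", {
  # uniform two-class prediction: ln 2, independent of labels
  y <- cbind(c(1, 0, 1), c(0, 1, 0))
  p <- matrix(0, 3, 2)
  expect_equal(softmax_loss(y, p), log(2), tolerance = 1e-12)
  y4 <- diag(4)
  expect_equal(softmax_loss(y4, matrix(1.7, 4, 4)), log(4), tolerance = 1e-12)

  # single pixel, y = (1,0), p = (1,0): -log(e/(e+1))
  expect_equal(softmax_loss(matrix(c(1, 0), 1), matrix(c(1, 0), 1)),
               -log(exp(1) / (exp(1) + 1)), tolerance = 1e-12)
  expect_equal(round(softmax_loss(matrix(c(1, 0), 1), matrix(c(1, 0), 1)), 4), 0.3133)

  # perfect-prediction limit
  expect_lt(softmax_loss(matrix(c(1, 0), 1), matrix(c(50, -50), 1)), 1e-8)

  # nonnegativity on random inputs
  set.seed(3)
  for (i in 1:20) {
    yy <- t(vapply(1:10, function(j) { v <- numeric(3); v[sample(3, 1)] <- 1; v }, numeric(3)))
    pp <- matrix(rnorm(30), 10, 3)
    expect_gte(softmax_loss(yy, pp), 0)
  }
  expect_error(softmax_loss(y, matrix(0, 2, 2)), "shapes")
})

test_that("build_model honours the shape contract and seeding", {
  cfg <- tiny_config()
  m1 <- build_model(cfg)
  m2 <- build_model(cfg)
  w1 <- cimtseg:::net_weights(m1$ptr)
  w2 <- cimtseg:::net_weights(m2$ptr)
  expect_equal(w1, w2, tolerance = 0)

  d <- cimtseg:::net_describe(m1$ptr)
  expect_equal(c(d$H, d$W), c(32, 64))

  s <- generate_phantom(tiny_spec(3))
  pm <- predict_probs(m1, make_pair(s$image))
  expect_identical(dim(pm), c(32L, 64L, 2L))
  expect_lt(max(abs(pm[, , 1] + pm[, , 2] - 1)), 1e-5)
  expect_true(all(pm >= 0 & pm <= 1))
  # reproducible prediction from seeded untrained weights
  pm2 <- predict_probs(m2, make_pair(s$image))
  expect_identical(pm, pm2)

  expect_error(model_config(input_shape = c(60, 100), encoder_blocks = 4), "divisible")
  expect_error(model_config(num_classes = 1), "num_classes")
})

test_that("binarize applies argmax with ties to background", {
  h <- 4; w <- 5
  pm <- array(0, c(h, w, 2))
  pm[, , 2] <- 0.6; pm[, , 1] <- 0.4
  expect_identical(binarize(pm), matrix(1L, h, w))
  pm[, , 2] <- 0.5; pm[, , 1] <- 0.5
  expect_identical(binarize(pm), matrix(0L, h, w))
  set.seed(8)
  pm[, , 2] <- runif(h * w); pm[, , 1] <- 1 - pm[, , 2]
  expect_identical(binarize(pm), matrix(as.integer(pm[, , 2] > 0.5), h, w))
  expect_error(binarize(array(0, c(4, 5, 3))), "H, W, 2")
})

test_that("training decreases the loss, improves Dice and is reproducible", {
  items <- phantom_items(8, tiny_spec(), seed = 100)
  cfg <- tiny_config(epochs = 4L, seed = 2L)
  aug <- augment_config(seed = 3)

  m0 <- build_model(cfg)
  test_item <- phantom_items(2, tiny_spec(), seed = 500)
  dice_untrained <- mean(vapply(test_item, function(it)
    dice(confusion(binarize(predict_probs(m0, it$pair)), it$mask)), numeric(1)))

  h1 <- train_model(m0, items, aug)
  expect_equal(nrow(h1), 4)
  expect_lt(h1$loss[4], h1$loss[1])

  dice_trained <- mean(vapply(test_item, function(it)
    dice(confusion(binarize(predict_probs(m0, it$pair)), it$mask)), numeric(1)))
  expect_gt(dice_trained, dice_untrained)

  # steps_per_epoch * batch_size samples consumed per epoch
  expect_equal(cfg$steps_per_epoch * cfg$batch_size, 20)

  # full determinism: fresh model, same seeds -> identical history
  m2 <- build_model(cfg)
  h2 <- train_model(m2, items, aug)
  expect_identical(h1, h2)

  expect_error(train_model(build_model(cfg), list()), "empty")
})

test_that("models round-trip through save/load", {
  items <- phantom_items(4, tiny_spec(), seed = 40)
  cfg <- tiny_config(epochs = 1L, seed = 5L)
  m <- build_model(cfg)
  train_model(m, items, augment_config(seed = 6))
  f <- tempfile(fileext = ".rds")
  on.exit(unlink(f))
  save_model(m, f)
  m2 <- load_model(f)
  pm1 <- predict_probs(m, items[[1]]$pair)
  pm2 <- predict_probs(m2, items[[1]]$pair)
  expect_equal(pm1, pm2, tolerance = 1e-6)
})
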