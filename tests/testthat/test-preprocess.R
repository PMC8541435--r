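test_that("crop_frame returns the requested sub-grid and checks bounds", {
  img <- normalize_image(matrix(runif(100 * 100, 0, 255), 100, 100))
  expect_identical(crop_frame(img, c(0, 0, 100, 100))$pixels, img$pixels)
  sub <- crop_frame(img, c(0, 0, 10, 20))
  expect_identical(dim(sub$pixels), c(10L, 20L))
  expect_identical(sub$pixels, img$pixels[1:10, 1:20])
  expect_equal(sub$pixel_density, img$pixel_density)
  expect_error(crop_frame(img, c(0, 90, 10, 20)), "bounds")
  expect_error(crop_frame(img, c(0, 0, 0, 20)), "positive")
})

test_that("normalize_image maps min-max to [0,1] with the constant convention", {
  g <- matrix(0:255, 16, 16)
  n <- normalize_image(g)
  expect_equal(range(n$pixels), c(0, 1))
  expect_equal(n$pixels[which(g == 255)[1]], 1.0)
  expect_equal(normalize_image(matrix(7, 4, 4))$pixels, matrix(0, 4, 4))
  expect_equal(as.vector(normalize_image(matrix(c(10, 20, 30), 1, 3))$pixels),
               c(0, 0.5, 1.0))
})

test_that("gradient_direction follows the atan2 mapping and conventions", {
  # vertical step edge: left half 0, right half 1 -> direction 0 rad -> 0.5
  step <- cbind(matrix(0, 10, 5), matrix(1, 10, 5))
  for (op in c("sobel", "prewitt")) {
    d <- gradient_direction(step, op)
    expect_identical(dim(d), dim(step))
    expect_true(all(d >= 0 & d <= 1))
    # interior rows at the edge columns see a pure +x gradient
    expect_equal(d[3:8, 5], rep(0.5, 6), tolerance = 1e-12)
    expect_equal(d[3:8, 6], rep(0.5, 6), tolerance = 1e-12)
  }
  # constant image: zero magnitude everywhere -> 0.5
  expect_equal(gradient_direction(matrix(0.3, 8, 8), "sobel"),
               matrix(0.5, 8, 8))
  # transpose symmetry: kernels swap g_x <-> g_y
  set.seed(5)
  img <- matrix(runif(12 * 15), 12, 15)
  kx <- cimtseg:::sobel_kx
  gx <- cimtseg:::correlate3(img, kx); gy <- cimtseg:::correlate3(img, t(kx))
  gxT <- cimtseg:::correlate3(t(img), kx); gyT <- cimtseg:::correlate3(t(img), t(kx))
  expect_equal(gxT, t(gy), tolerance = 1e-12)
  expect_equal(gyT, t(gx), tolerance = 1e-12)
  expect_error(gradient_direction(matrix(0, 2, 5)), "3x3")
})

test_that("make_pair differs only through the kernel coefficients", {
  set.seed(6)
  img <- normalize_image(matrix(runif(40 * 50), 40, 50))
  p <- make_pair(img)
  expect_identical(dim(p$sobel), dim(p$prewitt))
  expect_identical(p$sobel, gradient_direction(img, "sobel"))
  expect_identical(p$prewitt, gradient_direction(img, "prewitt"))
  cp <- make_pair(matrix(0.7, 16, 16))
  expect_equal(cp$sobel, matrix(0.5, 16, 16))
  expect_equal(cp$prewitt, matrix(0.5, 16, 16))
})

test_that("rasterize_mask connects points inclusively with half-up rounding", {
  ann <- boundary_annotation(li = rbind(c(0, 10), c(99, 10)),
                             ma = rbind(c(0, 14), c(99, 14)))
  m <- rasterize_mask(ann, c(100, 100))
  expect_true(all(colSums(m) == 5))
  expect_true(all(m[11:15, ] == 1L))

  # degenerate 1-px band when LI and MA coincide
  same <- boundary_annotation(li = rbind(c(0, 7), c(49, 7)),
                              ma = rbind(c(0, 7), c(49, 7)))
  m1 <- rasterize_mask(same, c(20, 50))
  expect_true(all(colSums(m1) == 1))

  # crossing interfaces rejected
  expect_error(boundary_annotation(li = rbind(c(0, 20), c(99, 20)),
                                   ma = rbind(c(0, 10), c(99, 10))),
               "annotation error")
  expect_error(rasterize_mask(ann, c(12, 100)), "bounds")
})

test_that("augment_pair is seeded, shape/binarity preserving, identity at zero", {
  s <- generate_phantom(phantom_spec(seed = 2))
  pair <- make_pair(s$image)
  zero <- augment_config(0, 0, 0, seed = 1)
  out <- augment_pair(pair, s$mask, zero, draw = 5)
  expect_equal(out$pair$sobel, pair$sobel, tolerance = 1e-12)
  expect_identical(out$mask, s$mask)

  cfg <- augment_config(seed = 9)
  a1 <- augment_pair(pair, s$mask, cfg, draw = 3)
  a2 <- augment_pair(pair, s$mask, cfg, draw = 3)
  expect_identical(a1$mask, a2$mask)
  expect_identical(a1$pair$prewitt, a2$pair$prewitt)
  a3 <- augment_pair(pair, s$mask, cfg, draw = 4)
  expect_false(identical(a3$mask, a1$mask) && identical(a3$pair$sobel, a1$pair$sobel))

  for (d in 1:100) {
    out <- augment_pair(pair, s$mask, cfg, draw = d)
    expect_identical(dim(out$mask), dim(s$mask))
    expect_true(all(out$mask %in% c(0L, 1L)))
    expect_true(all(out$pair$sobel >= 0 & out$pair$sobel <= 1))
  }
})

test_that("split_dataset partitions with a seeded shuffle", {
  items <- as.list(1:100)
  sp <- split_dataset(items, 0.8, seed = 4)
  expect_length(sp$train, 80)
  expect_length(sp$test, 20)
  expect_setequal(unlist(c(sp$train, sp$test)), 1:100)
  expect_length(intersect(unlist(sp$train), unlist(sp$test)), 0)

  sp5 <- split_dataset(as.list(1:5), 0.8, seed = 1)
  expect_length(sp5$train, 4)
  expect_length(sp5$test, 1)

  sp2 <- split_dataset(items, 0.8, seed = 4)
  expect_identical(sp, sp2)
  expect_error(split_dataset(list(), 0.8), "empty")
  expect_error(split_dataset(items, 1.2), "train_frac")
})
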