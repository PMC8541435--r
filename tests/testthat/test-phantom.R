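test_that("generation is deterministic and respects the stated geometry", {
  s1 <- generate_phantom(phantom_spec(seed = 1))
  s2 <- generate_phantom(phantom_spec(seed = 1))
  expect_identical(s1$image$pixels, s2$image$pixels)
  expect_identical(s1$mask, s2$mask)
  expect_identical(s1$annotation, s2$annotation)

  expect_true(all(s1$image$pixels >= 0 & s1$image$pixels <= 1))
  expect_identical(dim(s1$mask), dim(s1$image$pixels))

  # flat centerline at 0.6 mm x 16.66 px/mm: run length round(9.996) = 10
  flat <- generate_phantom(phantom_spec(thickness_mm = 0.6, curve_amplitude = 0))
  expect_identical(unique(column_runs(flat$mask)), 10L)

  # curved: every column within round(t) +/- 1
  for (sd in 1:5) {
    s <- generate_phantom(phantom_spec(seed = sd, thickness_mm = 0.55))
    runs <- column_runs(s$mask)
    expect_true(all(abs(runs - round(s$true_thickness_px)) <= 1))
  }
})

test_that("speckle-free limit reproduces the noiseless structure", {
  spec <- phantom_spec(speckle_looks = 1e6, seed = 7)
  s <- generate_phantom(spec)
  # independent reconstruction of the noiseless image from the mask rows
  bg <- cimtseg:::PHANTOM_BG
  band_level <- min(spec$contrast * bg, 0.85)
  edge <- min(band_level * cimtseg:::PHANTOM_EDGE_BOOST, 0.98)
  ref <- matrix(bg, spec$height, spec$width)
  for (j in seq_len(spec$width)) {
    fg <- which(s$mask[, j] == 1L)
    ref[seq_len(min(fg) - 1), j] <- cimtseg:::PHANTOM_LUMEN
    ref[fg, j] <- band_level
    ref[min(fg), j] <- edge
    ref[max(fg), j] <- edge
  }
  rms <- sqrt(mean((s$image$pixels - ref)^2))
  expect_lt(rms / sqrt(mean(ref^2)), 0.01)
})

test_that("annotation rasterizes back to the phantom mask", {
  for (sd in 1:8) {
    s <- generate_phantom(phantom_spec(seed = sd))
    rast <- rasterize_mask(s$annotation, dim(s$mask))
    disagree <- sum(rast != s$mask)
    expect_lt(disagree / sum(s$mask), 0.02)
    expect_gte(nrow(s$annotation$li), 10)
    # annotation points sit on the mask boundary
    for (q in seq_len(nrow(s$annotation$li))) {
      col <- s$annotation$li[q, 1] + 1
      fg <- which(s$mask[, col] == 1L)
      expect_equal(s$annotation$li[q, 2] + 1, min(fg))
      expect_equal(s$annotation$ma[q, 2] + 1, max(fg))
    }
  }
})

test_that("clean-mask thickness matches the spec'd truth within 1 px", {
  set.seed(42)
  for (sd in 1:6) {
    t_mm <- runif(1, 0.4, 1.0)
    s <- generate_phantom(phantom_spec(thickness_mm = t_mm, seed = sd))
    expect_lte(abs(image_thickness(s$mask, "max") - s$true_thickness_px), 1)
  }
})

test_that("invariant violations raise configuration errors naming the bound", {
  expect_error(phantom_spec(height = 16), "height")
  expect_error(phantom_spec(width = 32), "width")
  expect_error(phantom_spec(thickness_mm = 0.05), "2 px")
  expect_error(phantom_spec(curve_amplitude = 10, thickness_mm = 1.0), "0.2")
  expect_error(phantom_spec(lumen_depth_frac = 0.9), "lumen_depth_frac")
  expect_error(phantom_spec(contrast = 0.5), "contrast")
  expect_error(phantom_spec(speckle_looks = -1), "speckle_looks")
})

test_that("make_dataset is deterministic and samples stated intervals", {
  d1 <- make_dataset(5, list(thickness_mm = c(0.4, 1.0)), seed = 11)
  d2 <- make_dataset(5, list(thickness_mm = c(0.4, 1.0)), seed = 11)
  expect_identical(lapply(d1, `[[`, "mask"), lapply(d2, `[[`, "mask"))
  expect_identical(lapply(d1, function(s) s$image$pixels),
                   lapply(d2, function(s) s$image$pixels))
  t_px <- vapply(d1, `[[`, numeric(1), "true_thickness_px")
  expect_true(all(t_px >= 0.4 * 16.66 & t_px <= 1.0 * 16.66))
  # distinct speckle realizations
  expect_gt(length(unique(vapply(d1, function(s) s$image$pixels[1, 1], numeric(1)))), 1)

  expect_error(make_dataset(0), "n must be")
  expect_error(make_dataset(3, list(thickness_mm = c(1.0, 0.4))), "empty interval")
  expect_error(make_dataset(3, list(bogus = c(0, 1))), "unknown")
})

test_that("dataset round-trips through PGM/CSV/JSON on disk", {
  dir <- withr_tempdir()
  on.exit(unlink(dir, recursive = TRUE))
  d <- make_dataset(3, list(thickness_mm = c(0.5, 0.9)), seed = 3)
  write_dataset(d, dir)
  back <- read_dataset(dir)
  expect_length(back, 3)
  for (i in 1:3) {
    expect_identical(back[[i]]$mask, d[[i]]$mask)
    expect_identical(back[[i]]$annotation$li, d[[i]]$annotation$li)
    expect_equal(back[[i]]$true_thickness_px, d[[i]]$true_thickness_px)
    # 8-bit quantization only
    expect_lt(max(abs(back[[i]]$image$pixels - d[[i]]$image$pixels)), 1 / 255 + 1e-9)
  }
})
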