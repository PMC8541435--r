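# Preprocessing: raw image -> dual gradient-direction inputs, expert points ->
# binary label masks, paired augmentation, dataset split.
#
# Repo-wide coordinate convention: images are matrices with row 1 = top of the
# image; annotation coordinates are 0-based (column, row) pairs, row 0 = top.

#' Construct an ultrasound image object
#'
#' A thin container pairing a normalized intensity grid with the probe's pixel
#' density, the calibration constant used to convert pixel distances to mm.
#'
#' @param pixels numeric matrix, values in \[0,1\], row 1 = top.
#' @param pixel_density pixels per millimetre (default 16.66).
#' @return an `ultrasound_image` object.
#' @export
ultrasound_image <- function(pixels, pixel_density = 16.66) {
  if (!is.matrix(pixels) || !all(is.finite(pixels))) stop_cfg("pixels must be a finite numeric matrix")
  if (min(pixels) < 0 || max(pixels) > 1) stop_cfg("pixels must lie in [0,1]; call normalize_image() first")
  structure(list(pixels = pixels, pixel_density = pixel_density),
            class = "ultrasound_image")
}

as_pixels <- function(image) {
  if (inherits(image, "ultrasound_image")) image$pixels else image
}

#' @export
print.ultrasound_image <- function(x, ...) {
  cat(sprintf("ultrasound_image: %d x %d px, %.2f px/mm\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_density))
  invisible(x)
}

#' Construct a boundary annotation
#'
#' Ordered expert point lists for the lumen-intima (LI, upper) and
#' media-adventitia (MA, lower) interfaces of the intima-media complex.
#' Coordinates are 0-based `(column, row)` pairs.
#'
#' @param li,ma numeric matrices with two columns (column, row); at least two
#'   points each, columns strictly increasing.
#' @return a `boundary_annotation` object.
#' @export
boundary_annotation <- function(li, ma) {
  chk <- function(p, nm) {
    p <- matrix(as.numeric(p), ncol = 2, dimnames = NULL)
    if (nrow(p) < 2) stop_cfg("%s needs at least 2 points", nm)
    if (any(diff(p[, 1]) <= 0)) stop_cfg("%s columns must be strictly increasing", nm)
    p
  }
  ann <- structure(list(li = chk(li, "LI"), ma = chk(ma, "MA")),
                   class = "boundary_annotation")
  # LI must stay above (or on) MA over the shared column span
  lo <- max(min(ann$li[, 1]), min(ann$ma[, 1]))
  hi <- min(max(ann$li[, 1]), max(ann$ma[, 1]))
  if (lo <= hi) {
    cols <- seq(lo, hi, length.out = 64)
    li_r <- stats::approx(ann$li[, 1], ann$li[, 2], xout = cols)$y
    ma_r <- stats::approx(ann$ma[, 1], ann$ma[, 2], xout = cols)$y
    if (any(li_r > ma_r + 1e-9)) stop_cfg("annotation error: LI lies below MA on the shared span")
  }
  ann
}

#' Crop a sub-frame from an image
#'
#' Used to remove scanner UI frames with patient information before analysis.
#' `rect` is `(top, left, height, width)` with 0-based top/left.
#'
#' @param image an `ultrasound_image` or numeric matrix.
#' @param rect integer vector `(top, left, height, width)`.
#' @return cropped image of the same type; pixel density is preserved.
#' @export
crop_frame <- function(image, rect) {
  px <- as_pixels(image)
  rect <- as.integer(rect)
  if (length(rect) != 4) stop_cfg("rect must be (top, left, height, width)")
  top <- rect[1]; left <- rect[2]; h <- rect[3]; w <- rect[4]
  if (h <= 0 || w <= 0) stop_cfg("rect height and width must be positive")
  if (top < 0 || left < 0 || top + h > nrow(px) || left + w > ncol(px))
    stop_cfg("rect (%d,%d,%d,%d) outside image bounds %dx%d",
             top, left, h, w, nrow(px), ncol(px))
  out <- px[(top + 1):(top + h), (left + 1):(left + w), drop = FALSE]
  if (inherits(image, "ultrasound_image")) ultrasound_image(out, image$pixel_density) else out
}

#' Min-max normalize a raw intensity grid to \[0,1\]
#'
#' @param raw numeric matrix (any scale, e.g. 8-bit gray levels 0..255).
#' @param levels number of gray levels in the source (kept for provenance;
#'   the map is min-max, not a fixed division).
#' @param pixel_density pixels/mm for the returned image.
#' @return an `ultrasound_image`. A constant grid maps to all zeros.
#' @export
normalize_image <- function(raw, levels = 256, pixel_density = 16.66) {
  raw <- as_pixels(raw)
  if (length(raw) == 0) stop_cfg("empty grid")
  rng <- range(raw)
  px <- if (rng[1] == rng[2]) matrix(0, nrow(raw), ncol(raw)) else (raw - rng[1]) / (rng[2] - rng[1])
  ultrasound_image(px, pixel_density)
}

# 3x3 derivative kernels; g_x responds to left->right increase, g_y to
# top->bottom increase (rows grow downward).
sobel_kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
prewitt_kx <- matrix(c(-1, 0, 1, -1, 0, 1, -1, 0, 1), 3, 3, byrow = TRUE)

# 3x3 cross-correlation with replicate border padding, vectorized as nine
# shifted adds.
correlate3 <- function(px, k) {
  h <- nrow(px); w <- ncol(px)
  pad <- px[c(1, 1:h, h), c(1, 1:w, w)]
  out <- matrix(0, h, w)
  for (dr in -1:1) for (dc in -1:1) {
    kv <- k[dr + 2, dc + 2]
    if (kv != 0) out <- out + kv * pad[(2 + dr):(h + 1 + dr), (2 + dc):(w + 1 + dc)]
  }
  out
}

#' Gradient-direction image
#'
#' Applies the 3x3 Sobel or Prewitt derivative kernels (replicate-padded
#' borders) and keeps only the gradient *direction*,
#' `theta = atan2(g_y, g_x)`, mapped affinely from `(-pi, pi]` to `[0,1]`.
#' Pixels with zero gradient magnitude carry no orientation and map to 0.5,
#' the image of `theta = 0`.
#'
#' @param image an `ultrasound_image` or numeric matrix, at least 3x3.
#' @param operator `"sobel"` or `"prewitt"`.
#' @return numeric matrix in \[0,1\], same shape as the input.
#' @export
gradient_direction <- function(image, operator = c("sobel", "prewitt")) {
  operator <- match.arg(operator)
  px <- as_pixels(image)
  if (nrow(px) < 3 || ncol(px) < 3) stop_cfg("image must be at least 3x3 for a 3x3 kernel")
  kx <- if (operator == "sobel") sobel_kx else prewitt_kx
  gx <- correlate3(px, kx)
  gy <- correlate3(px, t(kx))
  theta <- atan2(gy, gx)
  dir <- (theta + pi) / (2 * pi)
  # flat regions: cancellation can leave ~1e-16 residues, so test magnitude
  # against a tolerance rather than exact zero
  tol <- 1e-9 * max(1, max(abs(px)))
  dir[abs(gx) < tol & abs(gy) < tol] <- 0.5
  dir
}

#' Build the model's dual gradient-direction input
#'
#' @param image an `ultrasound_image` or numeric matrix.
#' @return a `gradient_pair` object with fields `prewitt` and `sobel`, both
#'   matrices in \[0,1\] with the source image's shape.
#' @export
make_pair <- function(image) {
  structure(list(prewitt = gradient_direction(image, "prewitt"),
                 sobel = gradient_direction(image, "sobel")),
            class = "gradient_pair")
}

#' Rasterize a boundary annotation into a binary band mask
#'
#' LI and MA rows are linearly interpolated per column across each interface's
#' column span (connecting the expert points without a threshold); the band is
#' the inclusive row range `LI(c) <= r <= MA(c)`, restricted to columns covered
#' by both interfaces. Interpolated rows are rounded half-up.
#'
#' @param ann a `boundary_annotation`.
#' @param shape integer `(height, width)`.
#' @return 0/1 integer matrix of dimension `shape`.
#' @export
rasterize_mask <- function(ann, shape) {
  h <- shape[1]; w <- shape[2]
  pts <- rbind(ann$li, ann$ma)
  if (any(pts[, 1] < 0) || any(pts[, 1] > w - 1) || any(pts[, 2] < 0) || any(pts[, 2] > h - 1))
    stop_cfg("annotation points out of bounds for shape %dx%d", h, w)
  lo <- ceiling(max(min(ann$li[, 1]), min(ann$ma[, 1])))
  hi <- floor(min(max(ann$li[, 1]), max(ann$ma[, 1])))
  mask <- matrix(0L, h, w)
  if (lo > hi) return(mask)
  cols <- lo:hi
  li_r <- round_half_up(stats::approx(ann$li[, 1], ann$li[, 2], xout = cols)$y)
  ma_r <- round_half_up(stats::approx(ann$ma[, 1], ann$ma[, 2], xout = cols)$y)
  if (any(li_r > ma_r)) stop_cfg("annotation error: LI lies below MA after rasterization")
  for (i in seq_along(cols)) {
    mask[(li_r[i] + 1):(ma_r[i] + 1), cols[i] + 1] <- 1L
  }
  mask
}

#' Augmentation configuration
#'
#' Maximum magnitudes of the paired random transform applied during training:
#' rotation (degrees), width/height shift (fraction of the dimension) and zoom
#' deviation (fraction around 1).
#'
#' @param rotation_deg max absolute rotation in degrees (default 10).
#' @param shift_frac max shift as a fraction of width/height (default 0.2).
#' @param zoom_frac max zoom deviation (default 0.2; zoom in `[0.8, 1.2]`).
#' @param seed RNG seed for the augmentation stream.
#' @return an `augment_config` object.
#' @export
augment_config <- function(rotation_deg = 10, shift_frac = 0.2, zoom_frac = 0.2, seed = 1L) {
  if (rotation_deg < 0 || shift_frac < 0 || zoom_frac < 0) stop_cfg("augmentation magnitudes must be nonnegative")
  if (shift_frac >= 0.5) stop_cfg("shift_frac must be < 0.5")
  if (zoom_frac >= 1) stop_cfg("zoom_frac must be < 1")
  structure(list(rotation_deg = rotation_deg, shift_frac = shift_frac,
                 zoom_frac = zoom_frac, seed = as.integer(seed)),
            class = "augment_config")
}

# mirror (symmetric) index fold into 0..(n-1)
reflect_idx <- function(i, n) {
  p <- 2 * n
  j <- ((i %% p) + p) %% p
  ifelse(j >= n, p - 1 - j, j)
}

# Sample matrix `px` at 0-based fractional (row, col) coordinates with
# bilinear interpolation and symmetric boundary fill.
bilinear_sample <- function(px, rr, cc) {
  h <- nrow(px); w <- ncol(px)
  r0 <- floor(rr); c0 <- floor(cc)
  fr <- rr - r0; fc <- cc - c0
  ri0 <- reflect_idx(r0, h) + 1; ri1 <- reflect_idx(r0 + 1, h) + 1
  ci0 <- reflect_idx(c0, w) + 1; ci1 <- reflect_idx(c0 + 1, w) + 1
  v00 <- px[cbind(ri0, ci0)]; v01 <- px[cbind(ri0, ci1)]
  v10 <- px[cbind(ri1, ci0)]; v11 <- px[cbind(ri1, ci1)]
  (1 - fr) * ((1 - fc) * v00 + fc * v01) + fr * ((1 - fc) * v10 + fc * v11)
}

nearest_sample <- function(px, rr, cc) {
  ri <- reflect_idx(round_half_up(rr), nrow(px)) + 1
  ci <- reflect_idx(round_half_up(cc), ncol(px)) + 1
  px[cbind(ri, ci)]
}

#' Apply one paired random augmentation draw
#'
#' Draws rotation ~ U(-r, r) degrees, shifts ~ U(-s, s) x dimension and zoom ~
#' U(1-z, 1+z) from a stream determined by `(cfg$seed, draw)`, then applies the
#' *same* affine transform to both gradient images and the mask. Images are
#' resampled bilinearly with mirrored boundary fill; the mask uses
#' nearest-neighbour resampling and is re-binarized.
#'
#' @param pair a `gradient_pair`.
#' @param mask 0/1 matrix, same shape as the pair.
#' @param cfg an `augment_config`.
#' @param draw integer draw index; each index gives an independent transform.
#' @return list with fields `pair` and `mask`.
#' @export
augment_pair <- function(pair, mask, cfg, draw = 1L) {
  assert_mask(mask)
  if (!identical(dim(pair$sobel), dim(mask))) stop_cfg("pair and mask shapes differ")
  h <- nrow(mask); w <- ncol(mask)
  params <- withr_seed(derive_seed(cfg$seed, draw), function() {
    c(rot = runif(1, -cfg$rotation_deg, cfg$rotation_deg),
      sx = runif(1, -cfg$shift_frac, cfg$shift_frac) * w,
      sy = runif(1, -cfg$shift_frac, cfg$shift_frac) * h,
      zoom = runif(1, 1 - cfg$zoom_frac, 1 + cfg$zoom_frac))
  })
  theta <- params[["rot"]] * pi / 180
  z <- params[["zoom"]]
  cx <- (w - 1) / 2; cy <- (h - 1) / 2
  # inverse map: output pixel -> input pixel
  grid_c <- matrix(rep(0:(w - 1), each = h), h, w)
  grid_r <- matrix(rep(0:(h - 1), times = w), h, w)
  xo <- grid_c - cx - params[["sx"]]
  yo <- grid_r - cy - params[["sy"]]
  ct <- cos(theta); st <- sin(theta)
  xi <- (ct * xo + st * yo) / z + cx
  yi <- (-st * xo + ct * yo) / z + cy
  out_img <- function(px) matrix(bilinear_sample(px, as.vector(yi), as.vector(xi)), h, w)
  m <- matrix(nearest_sample(mask, as.vector(yi), as.vector(xi)), h, w)
  list(
    pair = structure(list(prewitt = out_img(pair$prewitt), sobel = out_img(pair$sobel)),
                     class = "gradient_pair"),
    mask = matrix(as.integer(m > 0.5), h, w)
  )
}

# run `fn` under a temporary RNG seed without disturbing the caller's RNG
withr_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Shuffle and split a dataset
#'
#' Seeded shuffle followed by a split at `round(n * train_frac)` (half-up).
#' The two parts are disjoint and exhaustive.
#'
#' @param items a list (or vector) of items.
#' @param train_frac fraction assigned to training (default 0.8).
#' @param seed RNG seed for the shuffle.
#' @return list with fields `train` and `test`.
#' @export
split_dataset <- function(items, train_frac = 0.8, seed = 1L) {
  n <- length(items)
  if (n == 0) stop_cfg("cannot split an empty dataset")
  if (n < 2) stop_cfg("need at least 2 items to form a train/test split")
  if (train_frac <= 0 || train_frac >= 1) stop_cfg("train_frac must be in (0,1)")
  perm <- withr_seed(derive_seed(seed, 0L), function() sample.int(n))
  n_train <- round_half_up(n * train_frac)
  n_train <- max(1L, min(n - 1L, as.integer(n_train)))
  list(train = items[perm[seq_len(n_train)]],
       test = items[perm[(n_train + 1):n]])
}
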