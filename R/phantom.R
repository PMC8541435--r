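# Synthetic carotid phantom: a dark lumen above a bright, slowly curving
# double-line band (the LI and MA interfaces) of known thickness, degraded by
# multiplicative gamma speckle.  Every downstream stage can therefore be
# exercised against exact ground truth without any clinical data.

#' Phantom specification
#'
#' Describes one synthetic B-mode-like image. Defaults are desk-scale
#' (64 x 128) with the clinical calibration of 16.66 pixels/mm and a band
#' thickness in the middle of the physiological 0.4-1.0 mm range.
#'
#' @param height,width image size in pixels (height >= 32, width >= 64).
#' @param pixel_density pixels per mm (default 16.66).
#' @param lumen_depth_frac fraction of the height at which the band's
#'   centerline sits, in (0.2, 0.8).
#' @param thickness_mm true band thickness in mm; `thickness_mm *
#'   pixel_density` must be at least 2 px.
#' @param curve_amplitude vertical sinusoidal deviation of the centerline, px.
#' @param curve_period period of the centerline sinusoid, px.
#' @param speckle_looks shape parameter of the mean-1 multiplicative gamma
#'   speckle; larger = smoother (fully developed speckle has looks ~ 1-16).
#' @param contrast ratio of band intensity to tissue background, in (1, 10].
#' @param seed integer RNG seed; the sample is a deterministic function of the
#'   spec including this seed.
#' @return a `phantom_spec` object.
#' @export
phantom_spec <- function(height = 64L, width = 128L, pixel_density = 16.66,
                         lumen_depth_frac = 0.5, thickness_mm = 0.7,
                         curve_amplitude = 2, curve_period = 96,
                         speckle_looks = 16, contrast = 4, seed = 1L) {
  spec <- structure(list(height = as.integer(height), width = as.integer(width),
                         pixel_density = pixel_density,
                         lumen_depth_frac = lumen_depth_frac,
                         thickness_mm = thickness_mm,
                         curve_amplitude = curve_amplitude,
                         curve_period = curve_period,
                         speckle_looks = speckle_looks,
                         contrast = contrast, seed = as.integer(seed)),
                    class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  with(spec, {
    if (height < 32) stop_cfg("phantom_spec: height must be >= 32 (got %d)", height)
    if (width < 64) stop_cfg("phantom_spec: width must be >= 64 (got %d)", width)
    if (pixel_density <= 0) stop_cfg("phantom_spec: pixel_density must be positive")
    if (lumen_depth_frac <= 0.2 || lumen_depth_frac >= 0.8)
      stop_cfg("phantom_spec: lumen_depth_frac must lie in (0.2, 0.8)")
    t_px <- thickness_mm * pixel_density
    if (t_px < 2) stop_cfg("phantom_spec: band thickness is %.2f px, below the 2 px minimum", t_px)
    if (curve_amplitude + t_px / 2 >= 0.2 * height)
      stop_cfg("phantom_spec: curve_amplitude + thickness/2 = %.1f px reaches the 0.2*height bound (%.1f px)",
               curve_amplitude + t_px / 2, 0.2 * height)
    if (curve_period <= 0) stop_cfg("phantom_spec: curve_period must be positive")
    if (speckle_looks <= 0) stop_cfg("phantom_spec: speckle_looks must be positive")
    if (contrast <= 1 || contrast > 10) stop_cfg("phantom_spec: contrast must lie in (1, 10]")
  })
  invisible(spec)
}

# intensity levels of the noiseless structure
PHANTOM_BG <- 0.18
PHANTOM_LUMEN <- 0.02
PHANTOM_EDGE_BOOST <- 1.15

# Band geometry. The sinusoidal centerline is sampled at sparse knot columns
# (the exported expert-style points); the per-column integer band rows are
# linear interpolations of the knots, rounded half-up -- exactly what
# rasterize_mask() does with the annotation, so annotation and mask agree by
# construction. At each knot the top row is round(center - t/2) and the run
# length is exactly round(t) pixels.
phantom_geometry <- function(spec, phase) {
  w <- spec$width
  t_px <- spec$thickness_mm * spec$pixel_density
  n_pts <- max(10L, as.integer(ceiling(w / 8)) + 1L)
  knot_cols <- unique(round(seq(0, w - 1, length.out = n_pts)))
  center <- spec$lumen_depth_frac * (spec$height - 1) +
    spec$curve_amplitude * sin(2 * pi * knot_cols / spec$curve_period + phase)
  li_k <- round_half_up(center - t_px / 2)
  ma_k <- li_k + round_half_up(t_px) - 1
  cols <- 0:(w - 1)
  li <- round_half_up(stats::approx(knot_cols, li_k, xout = cols)$y)
  ma <- round_half_up(stats::approx(knot_cols, ma_k, xout = cols)$y)
  list(knot_cols = knot_cols, li_k = li_k, ma_k = ma_k, li = li, ma = ma)
}

phantom_structure <- function(spec, band) {
  h <- spec$height; w <- spec$width
  band_level <- min(spec$contrast * PHANTOM_BG, 0.85)
  img <- matrix(PHANTOM_BG, h, w)
  for (j in seq_len(w)) {
    li <- band[["li"]][j]; ma <- band[["ma"]][j]
    img[seq_len(li), j] <- PHANTOM_LUMEN            # lumen above the band
    img[(li + 1):(ma + 1), j] <- band_level          # bright IMC band
    # 1-px brighter LI/MA edges give the gradient operators the double-line
    # structure real scans show
    edge <- min(band_level * PHANTOM_EDGE_BOOST, 0.98)
    img[li + 1, j] <- edge
    img[ma + 1, j] <- edge
  }
  img
}

#' Generate one synthetic phantom sample
#'
#' Deterministic given the spec (including its seed). The returned sample
#' carries the image, the exact band mask, a sparse expert-style boundary
#' annotation and the true thickness in pixels.
#'
#' @param spec a `phantom_spec`.
#' @return a `phantom_sample`: list with `image` (an `ultrasound_image`),
#'   `mask` (0/1 matrix), `annotation` (a `boundary_annotation`),
#'   `true_thickness_px`, and `spec`.
#' @export
generate_phantom <- function(spec) {
  validate_phantom_spec(spec)
  h <- spec$height; w <- spec$width
  sample_data <- withr_seed(spec$seed, function() {
    phase <- runif(1, 0, 2 * pi)
    band <- phantom_geometry(spec, phase)
    clean <- phantom_structure(spec, band)
    speckle <- matrix(rgamma(h * w, shape = spec$speckle_looks,
                             rate = spec$speckle_looks), h, w)
    list(band = band, img = clamp01(clean * speckle))
  })
  band <- sample_data$band
  mask <- matrix(0L, h, w)
  for (j in seq_len(w)) mask[(band$li[j] + 1):(band$ma[j] + 1), j] <- 1L

  # sparse expert-style points: >= 10 evenly spaced columns incl. both ends
  ann <- boundary_annotation(
    li = cbind(band$knot_cols, band$li_k),
    ma = cbind(band$knot_cols, band$ma_k)
  )
  structure(list(
    image = ultrasound_image(sample_data$img, spec$pixel_density),
    mask = mask,
    annotation = ann,
    true_thickness_px = spec$thickness_mm * spec$pixel_density,
    spec = spec
  ), class = "phantom_sample")
}

#' Generate a dataset of phantom samples
#'
#' Per-sample spec fields are drawn uniformly from the supplied intervals;
#' per-sample seeds are derived deterministically from `seed`, so the whole
#' dataset is reproducible.
#'
#' @param n number of samples (>= 1).
#' @param spec_ranges named list of `c(min, max)` intervals for numeric
#'   `phantom_spec` fields (e.g. `list(thickness_mm = c(0.4, 1.0))`); fields
#'   not listed use `base_spec`'s value.
#' @param seed master RNG seed.
#' @param base_spec template `phantom_spec` supplying fixed fields.
#' @return list of `phantom_sample` objects.
#' @export
make_dataset <- function(n, spec_ranges = list(thickness_mm = c(0.4, 1.0)),
                         seed = 1L, base_spec = phantom_spec()) {
  if (n < 1) stop_cfg("n must be >= 1")
  numeric_fields <- c("pixel_density", "lumen_depth_frac", "thickness_mm",
                      "curve_amplitude", "curve_period", "speckle_looks", "contrast")
  for (nm in names(spec_ranges)) {
    if (!nm %in% numeric_fields) stop_cfg("unknown or non-numeric spec field in ranges: %s", nm)
    rng <- spec_ranges[[nm]]
    if (length(rng) != 2 || rng[2] < rng[1]) stop_cfg("empty interval for field %s", nm)
  }
  draws <- withr_seed(derive_seed(seed, 1L), function() {
    lapply(seq_len(n), function(i) {
      vapply(spec_ranges, function(rng) runif(1, rng[1], rng[2]), numeric(1))
    })
  })
  lapply(seq_len(n), function(i) {
    sp <- base_spec
    for (nm in names(spec_ranges)) sp[[nm]] <- unname(draws[[i]][[nm]])
    sp$seed <- derive_seed(seed, i + 1L)
    class(sp) <- "phantom_spec"
    validate_phantom_spec(sp)
    generate_phantom(sp)
  })
}

#' Write a phantom dataset to disk
#'
#' Images as ASCII PGM, masks as 0/255 PGM, annotations as
#' `interface,column,row` CSV, plus a JSON manifest listing paths, seeds and
#' true thicknesses.
#'
#' @param samples list of `phantom_sample` objects.
#' @param dir output directory (created if missing).
#' @return the manifest path, invisibly.
#' @export
write_dataset <- function(samples, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- lapply(seq_along(samples), function(i) {
    s <- samples[[i]]
    id <- sprintf("phantom_%03d", i)
    img_p <- file.path(dir, paste0(id, ".pgm"))
    msk_p <- file.path(dir, paste0(id, "_mask.pgm"))
    ann_p <- file.path(dir, paste0(id, "_annotation.csv"))
    write_pgm(s$image$pixels, img_p)
    write_mask(s$mask, msk_p)
    write_annotation(s$annotation, ann_p)
    list(id = id, image = basename(img_p), mask = basename(msk_p),
         annotation = basename(ann_p), seed = s$spec$seed,
         true_thickness_px = s$true_thickness_px,
         pixel_density = s$spec$pixel_density)
  })
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(entries, manifest, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read a phantom dataset written by [write_dataset()]
#' @param dir dataset directory containing `manifest.json`.
#' @return list of samples (image, mask, annotation, true_thickness_px).
#' @export
read_dataset <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = FALSE)
  lapply(manifest, function(e) {
    list(
      image = ultrasound_image(read_pgm(file.path(dir, e$image)), e$pixel_density),
      mask = read_mask(file.path(dir, e$mask)),
      annotation = read_annotation(file.path(dir, e$annotation)),
      true_thickness_px = e$true_thickness_px,
      id = e$id
    )
  })
}
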