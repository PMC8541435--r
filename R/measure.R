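# cIMT measurement: column-wise run lengths on the final band mask, converted
# to millimetres with the scanner's pixel density, and compared against expert
# reference means.

#' Per-column foreground run length
#'
#' For each column, the length in pixels of the longest contiguous vertical
#' run of foreground; 0 for empty columns. This is the literal distance from
#' the band's upper to lower boundary at that column.
#'
#' @param mask 0/1 matrix.
#' @return integer vector of length `ncol(mask)`.
#' @export
column_runs <- function(mask) {
  assert_mask(mask)
  apply(mask, 2L, function(col) {
    r <- rle(as.integer(col))
    runs <- r$lengths[r$values == 1L]
    if (length(runs) == 0) 0L else max(runs)
  })
}

#' Thickness of one image's band, in pixels
#'
#' @param mask 0/1 matrix with at least one foreground pixel.
#' @param mode `"max"` (the per-image local maximum run, default) or `"mean"`
#'   (mean run over nonempty columns).
#' @return thickness in pixels.
#' @export
image_thickness <- function(mask, mode = c("max", "mean")) {
  mode <- match.arg(mode)
  runs <- column_runs(mask)
  runs <- runs[runs > 0]
  if (length(runs) == 0) stop_cfg("no IMC detected: mask has no foreground pixels")
  if (mode == "max") as.numeric(max(runs)) else mean(runs)
}

#' Cohort mean thickness in pixels
#' @param per_image_px numeric vector of per-image thicknesses.
#' @return arithmetic mean.
#' @export
cohort_mean <- function(per_image_px) {
  if (length(per_image_px) == 0) stop_cfg("empty thickness list")
  mean(per_image_px)
}

#' Convert a pixel distance to millimetres
#' @param px distance in pixels.
#' @param density pixel density in pixels/mm (default 16.66).
#' @return distance in mm.
#' @export
px_to_mm <- function(px, density = 16.66) {
  if (density <= 0) stop_cfg("pixel density must be positive")
  px / density
}

#' Absolute error against an expert reference mean, in mm
#'
#' @param measured_mm measured cohort mean IMT in mm.
#' @param ref_mm expert reference mean in mm (or an `expert_reference`).
#' @return `|measured - reference|`, rounded to 2 decimals (reporting
#'   convention of clinical IMT tables).
#' @export
expert_error <- function(measured_mm, ref_mm) {
  if (inherits(ref_mm, "expert_reference")) ref_mm <- ref_mm$mean_mm
  if (measured_mm <= 0 || ref_mm <= 0) stop_cfg("IMT values must be positive")
  round(abs(measured_mm - ref_mm), 2)
}

#' An expert reference measurement
#' @param label free-text label (e.g. "Expert 2, time 12").
#' @param mean_mm mean IMT in mm, > 0.
#' @return an `expert_reference` object.
#' @export
expert_reference <- function(label, mean_mm) {
  if (mean_mm <= 0) stop_cfg("mean_mm must be positive")
  structure(list(label = label, mean_mm = mean_mm), class = "expert_reference")
}

#' Thickness report over a set of masks
#'
#' @param masks list of 0/1 matrices (final, refined predictions).
#' @param pixel_density pixels/mm.
#' @param mode per-image thickness mode, see [image_thickness()].
#' @param experts optional list of `expert_reference`s to difference against.
#' @return a `thickness_report`: per-image pixels, cohort mean in px and mm,
#'   and an expert-error table when references are given.
#' @export
thickness_report <- function(masks, pixel_density = 16.66, mode = "max",
                             experts = NULL) {
  per_image <- vapply(masks, image_thickness, numeric(1), mode = mode)
  mean_px <- cohort_mean(per_image)
  mean_mm <- px_to_mm(mean_px, pixel_density)
  errs <- NULL
  if (!is.null(experts)) {
    errs <- data.frame(
      label = vapply(experts, function(e) e$label, character(1)),
      expert_mm = vapply(experts, function(e) e$mean_mm, numeric(1)),
      error_mm = vapply(experts, function(e) expert_error(mean_mm, e), numeric(1))
    )
  }
  structure(list(per_image_px = per_image, mean_px = mean_px,
                 mean_mm = mean_mm, pixel_density = pixel_density,
                 mode = mode, expert_errors = errs),
            class = "thickness_report")
}

#' @export
print.thickness_report <- function(x, ...) {
  cat(sprintf("cIMT over %d images (%s mode): %.3f px = %.3f mm at %.2f px/mm\n",
              length(x$per_image_px), x$mode, x$mean_px, x$mean_mm, x$pixel_density))
  if (!is.null(x$expert_errors)) {
    cat("expert errors (mm):\n")
    print(x$expert_errors, row.names = FALSE)
  }
  invisible(x)
}
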