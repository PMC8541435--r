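# Morphological refinement of predicted band masks.
#
# Flat rectangular structuring elements (SE) only, which makes erosion and
# dilation separable into a vertical and a horizontal min/max filter. Border
# convention: each operation pads with its neutral element (dilation with
# background 0, erosion with foreground 1), so closing is extensive and
# opening anti-extensive everywhere, and a band that runs into the image's
# left/right edge is not eaten by a wide SE.
#
# SE anchor for size s: left/top reach floor((s-1)/2), right/bottom reach
# s-1-floor((s-1)/2) (an even SE extends one pixel further right/down).

se_reach <- function(s) {
  left <- (s - 1L) %/% 2L
  c(left, s - 1L - left)
}

# directional running min/max over explicit offsets with out-of-bounds fill
run_filter_rows <- function(mask, offsets, fun, fill) {
  h <- nrow(mask); w <- ncol(mask)
  out <- mask
  for (o in offsets) {
    if (o == 0) next
    shifted <- matrix(fill, h, w)
    if (o > 0 && o < h) shifted[1:(h - o), ] <- mask[(1 + o):h, ]
    if (o < 0 && -o < h) shifted[(1 - o):h, ] <- mask[1:(h + o), ]
    out <- fun(out, shifted)
  }
  out
}

run_filter_cols <- function(mask, offsets, fun, fill) {
  h <- nrow(mask); w <- ncol(mask)
  out <- mask
  for (o in offsets) {
    if (o == 0) next
    shifted <- matrix(fill, h, w)
    if (o > 0 && o < w) shifted[, 1:(w - o)] <- mask[, (1 + o):w]
    if (o < 0 && -o < w) shifted[, (1 - o):w] <- mask[, 1:(w + o)]
    out <- fun(out, shifted)
  }
  out
}

# Erosion is Minkowski subtraction by the SE footprint O (offsets
# -left..+right); dilation is Minkowski addition, i.e. the max filter over the
# *reflected* footprint -O.  Pairing them this way keeps closing extensive and
# opening anti-extensive for even SE sizes too (an unreflected pair would
# shift the band by one pixel per close/open).
erode_mask <- function(mask, se) {
  rv <- se_reach(se[1]); rh <- se_reach(se[2])
  m <- run_filter_rows(mask, seq(-rv[1], rv[2]), pmin, 1L)
  run_filter_cols(m, seq(-rh[1], rh[2]), pmin, 1L)
}

dilate_mask <- function(mask, se) {
  rv <- se_reach(se[1]); rh <- se_reach(se[2])
  m <- run_filter_rows(mask, seq(-rv[2], rv[1]), pmax, 0L)
  run_filter_cols(m, seq(-rh[2], rh[1]), pmax, 0L)
}

#' A single morphological step
#'
#' @param op `"close"` (dilate then erode, bridges gaps) or `"open"` (erode
#'   then dilate, removes small noise).
#' @param se_shape integer `(height, width)` of the flat rectangular SE.
#' @return a `morph_step` object.
#' @export
morph_step <- function(op = c("close", "open"), se_shape) {
  op <- match.arg(op)
  se_shape <- as.integer(se_shape)
  if (length(se_shape) != 2 || any(se_shape < 1)) stop_cfg("se_shape must be two integers >= 1")
  structure(list(op = op, se_shape = se_shape), class = "morph_step")
}

#' Apply one morphological step to a binary mask
#'
#' @param mask 0/1 matrix.
#' @param step a `morph_step`.
#' @return refined 0/1 matrix, same shape.
#' @export
morph_apply <- function(mask, step) {
  assert_mask(mask)
  se <- step$se_shape
  if (se[1] > nrow(mask) || se[2] > ncol(mask))
    stop_cfg("structuring element %dx%d larger than image %dx%d",
             se[1], se[2], nrow(mask), ncol(mask))
  mask <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  out <- if (step$op == "close") erode_mask(dilate_mask(mask, se), se)
         else dilate_mask(erode_mask(mask, se), se)
  out
}

#' Default refinement chain for predicted IMC masks
#'
#' Close (2,30) to bridge discontinued band segments, open (2,30) to drop
#' small speckle-induced noise, then close (3,30) to consolidate the band.
#'
#' @return list of `morph_step` objects.
#' @export
default_morph_chain <- function() {
  list(morph_step("close", c(2, 30)),
       morph_step("open", c(2, 30)),
       morph_step("close", c(3, 30)))
}

#' Refine a predicted mask with the morphological chain
#'
#' @param mask 0/1 matrix.
#' @param chain list of `morph_step`s (default [default_morph_chain()]).
#' @return refined 0/1 matrix.
#' @export
refine <- function(mask, chain = default_morph_chain()) {
  for (step in chain) mask <- morph_apply(mask, step)
  mask
}
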