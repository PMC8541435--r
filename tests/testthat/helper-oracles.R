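# Brute-force oracles, kept deliberately naive and independent of the package
# implementations they check.

# --- morphology -------------------------------------------------------------
# Same conventions as the package: SE of size s has footprint offsets
# -floor((s-1)/2) .. s-1-floor((s-1)/2); erosion is the min filter over the
# footprint (fill 1 outside), dilation the max filter over the *reflected*
# footprint (fill 0), i.e. Minkowski subtraction/addition by the same SE.

oracle_reach <- function(s) {
  left <- (s - 1L) %/% 2L
  c(left, s - 1L - left)
}

oracle_filter <- function(mask, se, fun, fill, reflect) {
  h <- nrow(mask); w <- ncol(mask)
  rv <- oracle_reach(se[1]); rh <- oracle_reach(se[2])
  drs <- -rv[1]:rv[2]; dcs <- -rh[1]:rh[2]
  if (reflect) { drs <- -drs; dcs <- -dcs }
  pr <- max(abs(drs), 0); pc <- max(abs(dcs), 0)
  pad <- matrix(fill, h + 2 * pr, w + 2 * pc)
  pad[pr + (1:h), pc + (1:w)] <- mask
  out <- matrix(0L, h, w)
  for (r in 1:h) for (c in 1:w)
    out[r, c] <- fun(pad[r + pr + drs, c + pc + dcs])
  out
}

oracle_dilate <- function(mask, se) oracle_filter(mask, se, max, 0L, reflect = TRUE)
oracle_erode <- function(mask, se) oracle_filter(mask, se, min, 1L, reflect = FALSE)
oracle_close <- function(mask, se) oracle_erode(oracle_dilate(mask, se), se)
oracle_open <- function(mask, se) oracle_dilate(oracle_erode(mask, se), se)

# --- metrics ----------------------------------------------------------------
# Set-operation oracle on explicit pixel index sets.

oracle_metrics <- function(pred, gt) {
  A <- which(pred == 1L)
  B <- which(gt == 1L)
  inter <- length(intersect(A, B))
  uni <- length(union(A, B))
  dice <- if (length(A) + length(B) == 0) 1 else 2 * inter / (length(A) + length(B))
  jac <- if (uni == 0) 1 else inter / uni
  prec <- if (length(A) == 0) 0 else inter / length(A)
  rec <- if (length(B) == 0) 0 else inter / length(B)
  f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  list(precision = prec, recall = rec, f1 = f1, dice = dice, jaccard = jac)
}

random_mask <- function(h, w, p = 0.3) {
  matrix(as.integer(runif(h * w) < p), h, w)
}

# --- misc fixtures ----------------------------------------------------------

# horizontal band mask: rows r0..r1 (1-based) set across all columns
band_mask <- function(h, w, r0, r1) {
  m <- matrix(0L, h, w)
  m[r0:r1, ] <- 1L
  m
}

# small phantom training items for network tests
phantom_items <- function(n, spec, seed = 1L) {
  lapply(seq_len(n), function(i) {
    s <- generate_phantom(modifyList_spec(spec, list(seed = seed + i)))
    list(pair = make_pair(s$image), mask = s$mask,
         true_thickness_px = s$true_thickness_px)
  })
}

modifyList_spec <- function(spec, changes) {
  for (nm in names(changes)) spec[[nm]] <- changes[[nm]]
  class(spec) <- "phantom_spec"
  spec
}

withr_tempdir <- function() {
  d <- tempfile("cimtseg")
  dir.create(d)
  d
}

# tiny model config for fast network tests (32 x 64 input)
tiny_config <- function(epochs = 4L, seed = 1L) {
  model_config(input_shape = c(32L, 64L), encoder_blocks = 3L,
               base_filters = 8L, learning_rate = 1e-3, batch_size = 4L,
               epochs = epochs, steps_per_epoch = 5L, seed = seed)
}

tiny_spec <- function(seed = 1L) {
  phantom_spec(height = 32L, width = 64L, thickness_mm = 0.5,
               curve_amplitude = 1, curve_period = 48, seed = seed)
}
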