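# Internal helpers shared across modules.

# Round half away from zero (for nonnegative inputs: round half up).
# base::round() rounds half to even, which is the wrong convention for
# rasterizing boundary rows.
round_half_up <- function(x) floor(x + 0.5)

# Derive a child seed from a master seed and a stream index.  Plain LCG-style
# mixing keeps everything inside 32-bit integer range so set.seed() accepts it.
derive_seed <- function(seed, stream) {
  m <- 2147483647
  x <- (as.numeric(seed) %% m) * 48271 + as.numeric(stream) * 16807 + 12345
  as.integer(x %% m)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

stop_cfg <- function(...) stop(sprintf(...), call. = FALSE)

is_binary_mask <- function(m) {
  is.matrix(m) && all(m %in% c(0L, 1L, 0, 1))
}

assert_mask <- function(m, name = "mask") {
  if (!is_binary_mask(m)) stop_cfg("%s must be a binary 0/1 matrix", name)
  invisible(TRUE)
}
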