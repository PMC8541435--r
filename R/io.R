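# Plain-text image and annotation I/O.
#
# Images are stored as ASCII PGM (P2), a codec-free grayscale format that is
# readable everywhere.  Matrices are row-down, column-right, values in [0,1]
# internally; files hold 8-bit levels 0..255 (masks use 0/255).

#' Write a grayscale image as ASCII PGM (P2)
#'
#' @param img numeric matrix with values in \[0,1\] (row 0 = top).
#' @param path output file path.
#' @param maxval maximum gray level written to the file.
#' @return `path`, invisibly.
#' @export
write_pgm <- function(img, path, maxval = 255L) {
  if (!is.matrix(img)) stop_cfg("img must be a matrix")
  lev <- round(clamp01(img) * maxval)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(img), nrow(img)), as.character(maxval)), con)
  # one image row per line
  writeLines(apply(lev, 1L, paste, collapse = " "), con)
  invisible(path)
}

#' Read an ASCII PGM (P2) image
#'
#' @param path file path.
#' @return numeric matrix with values scaled to \[0,1\].
#' @export
read_pgm <- function(path) {
  toks <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  if (toks[1] != "P2") stop_cfg("not an ASCII PGM (P2) file: %s", path)
  w <- as.integer(toks[2]); h <- as.integer(toks[3])
  maxval <- as.numeric(toks[4])
  vals <- as.numeric(toks[-(1:4)])
  if (length(vals) != w * h) stop_cfg("corrupt PGM: expected %d pixels, got %d", w * h, length(vals))
  matrix(vals, nrow = h, ncol = w, byrow = TRUE) / maxval
}

#' Write a binary band mask as a 0/255 PGM
#' @param mask 0/1 integer matrix.
#' @param path output path.
#' @export
write_mask <- function(mask, path) {
  assert_mask(mask)
  write_pgm(mask, path)
}

#' Read a band mask from a PGM written by [write_mask()]
#' @param path file path.
#' @return 0/1 integer matrix.
#' @export
read_mask <- function(path) {
  m <- read_pgm(path)
  matrix(as.integer(m > 0.5), nrow = nrow(m))
}

#' Write a boundary annotation as CSV
#'
#' File format: header `interface,column,row`; `interface` is `LI` or `MA`;
#' `column`/`row` are 0-based pixel coordinates (row 0 = top).
#'
#' @param ann a `boundary_annotation` object.
#' @param path output path.
#' @export
write_annotation <- function(ann, path) {
  df <- rbind(
    data.frame(interface = "LI", column = ann$li[, 1], row = ann$li[, 2]),
    data.frame(interface = "MA", column = ann$ma[, 1], row = ann$ma[, 2])
  )
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a boundary annotation CSV
#' @param path file path (format of [write_annotation()]).
#' @return a `boundary_annotation` object.
#' @export
read_annotation <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("interface", "column", "row")
  if (!all(need %in% names(df))) stop_cfg("annotation CSV must have columns %s", paste(need, collapse = ","))
  boundary_annotation(
    li = as.matrix(df[df$interface == "LI", c("column", "row")]),
    ma = as.matrix(df[df$interface == "MA", c("column", "row")])
  )
}
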