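#' @keywords internal
"_PACKAGE"

#' @import stats
#' @import utils
NULL

# Derive a 32-bit substream seed for one eye from the study seed, so each
# eye is reproducible on its own and insensitive to generation order.
eye_seed <- function(seed, eye_index) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  as.integer((abs(seed) * 48271 + eye_index * 16807) %% 2147483647)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

abort_input <- function(...) stop(..., call. = FALSE)

# Round to 3 significant figures for display, matching the convention used
# in published group tables (percentages and ratios).
signif3 <- function(x) signif(x, 3L)

#' Read a grayscale image
#'
#' Reads a single-channel grayscale TIFF or PNG into an intensity matrix on
#' the original bit-depth scale (0-255 for 8-bit, 0-65535 for 16-bit).
#' Multi-channel images are reduced to their first channel.
#'
#' @param path Path to a `.tif`/`.tiff` or `.png` file.
#' @return Numeric matrix of intensities, rows = image rows (y), columns = x.
#' @export
read_gray <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = ,
    tiff = tiff::readTIFF(path, info = TRUE),
    png = png::readPNG(path),
    abort_input("unsupported image format: ", ext)
  )
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  attr <- attributes(img)
  bps <- attr$bits.per.sample %||% 8L
  m <- img * (2^bps - 1)
  dim(m) <- dim(img)[1:2]
  m
}

#' Write a grayscale image
#'
#' Writes an intensity matrix (0..2^bits-1 scale) as a single-channel
#' grayscale TIFF or PNG.
#'
#' @param img Numeric intensity matrix.
#' @param path Output path; the extension selects the format.
#' @param bits Bit depth, 8 or 16.
#' @return `path`, invisibly.
#' @export
write_gray <- function(img, path, bits = 8L) {
  stopifnot(bits %in% c(8L, 16L))
  maxv <- 2^bits - 1
  scaled <- pmin(pmax(img, 0), maxv) / maxv
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = ,
    tiff = tiff::writeTIFF(scaled, path, bits.per.sample = as.integer(bits)),
    png = png::writePNG(scaled, path),
    abort_input("unsupported image format: ", ext)
  )
  invisible(path)
}
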