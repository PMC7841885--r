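# Raster I/O: 8-bit PNG/TIFF images in, 16-bit single-channel TIFF (or
# PNG) label masks out. All intensities are scaled to [0, 255] on read.

#' Read an image file as an intensity raster
#'
#' Supports 8-bit PNG and TIFF, grayscale or RGB. Values are rescaled
#' from the decoder's `[0, 1]` to `[0, 255]` and rounded; an alpha
#' channel, if present, is dropped.
#'
#' @param path file path (`.png`, `.tif`/`.tiff`).
#' @return an intensity matrix (grayscale input) or
#'   `height x width x 3` array (RGB input).
#' @export
readGrayImage <- function(path) {
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    stop("unsupported image format '.", ext, "'", call. = FALSE))
  if (length(dim(x)) == 3L) {
    if (dim(x)[3L] %in% c(2L, 4L))   # drop alpha
      x <- x[, , -dim(x)[3L], drop = FALSE]
    if (dim(x)[3L] == 1L) x <- x[, , 1L]
  }
  round(x * 255)
}

#' Write a grayscale image as 8-bit PNG
#'
#' @param img intensity matrix in `[0, 255]`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGrayImage <- function(img, path) {
  stopifnot(is.matrix(img), min(img) >= 0, max(img) <= 255)
  png::writePNG(img / 255, path)
  invisible(path)
}

#' Read / write instance label masks
#'
#' Label masks are stored as 16-bit single-channel rasters whose pixel
#' value is the instance label (0 = background). `writeLabelMask` writes
#' TIFF (or PNG by extension); `readLabelMask` rescales by the stored
#' bit depth and re-indexes the labels to a contiguous `1..K`.
#'
#' @param mask integer label mask.
#' @param path file path (`.tif`/`.tiff` or `.png`).
#' @return `readLabelMask` returns an integer matrix; `writeLabelMask`
#'   invisibly returns `path`.
#' @export
writeLabelMask <- function(mask, path) {
  stopifnot(is.matrix(mask), min(mask) >= 0, max(mask) <= 65535)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = , tiff = tiff::writeTIFF(mask / 65535, path,
                                   bits.per.sample = 16L),
    png = {
      if (max(mask) > 255)
        stop("PNG masks are written 8-bit; > 255 labels need TIFF",
             call. = FALSE)
      png::writePNG(mask / 255, path)
    },
    stop("unsupported mask format '.", ext, "'", call. = FALSE))
  invisible(path)
}

#' @rdname writeLabelMask
#' @export
readLabelMask <- function(path) {
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    png = {
      v <- png::readPNG(path, info = TRUE)
      depth <- attr(v, "info")$bit.depth
      if (is.null(depth)) depth <- 8L
      v * (2^depth - 1)
    },
    tif = , tiff = tiff::readTIFF(path) * 65535,
    stop("unsupported mask format '.", ext, "'", call. = FALSE))
  if (length(dim(x)) == 3L) x <- x[, , 1L]
  .relabel(round(x))
}
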