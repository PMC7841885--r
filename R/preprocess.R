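#' Convert an input raster to the working grayscale image
#'
#' RGB input is reduced to its green channel, which carries the most
#' nucleus contrast in Papanicolaou-stained material; grayscale input is
#' returned unchanged (already-grayscale datasets need no conversion).
#'
#' @param img a numeric matrix of intensities in `[0, 255]`, or an
#'   `height x width x channels` array with 1 or 3 channels.
#' @return a numeric matrix of intensities in `[0, 255]`.
#' @examples
#' rgb <- array(c(10, 200, 30), dim = c(1, 1, 3))
#' rgb <- rgb[rep(1, 8), rep(1, 8), , drop = FALSE]
#' toGrayscale(rgb)[1, 1]  # 200, the green value
#' @export
toGrayscale <- function(img) {
  if (is.matrix(img)) {
    g <- img
  } else if (is.array(img) && length(dim(img)) == 3L) {
    nch <- dim(img)[3L]
    if (nch == 1L) g <- img[, , 1L]
    else if (nch == 3L) g <- img[, , 2L]
    else stop("unsupported channel count: ", nch, call. = FALSE)
  } else {
    stop("'img' must be a matrix or a 3-D array", call. = FALSE)
  }
  if (!is.numeric(g) || anyNA(g) || min(g) < 0 || max(g) > 255)
    stop("intensities must be numeric in [0, 255] (8-bit)", call. = FALSE)
  g
}

#' Gaussian smoothing of a grayscale image
#'
#' Separable Gaussian convolution with edge-inclusive reflect padding;
#' sigma is derived from the kernel size. Output is rounded back to whole
#' intensity levels, keeping the image 8-bit throughout the pipeline.
#'
#' @param img grayscale intensity matrix.
#' @param kernel odd kernel side length in pixels; `1` returns the input
#'   unchanged.
#' @return a smoothed intensity matrix of the same shape.
#' @examples
#' m <- matrix(0, 5, 5); m[3, 3] <- 255
#' gaussianBlur(m, 3)
#' @export
gaussianBlur <- function(img, kernel = 5) {
  stopifnot(is.matrix(img))
  if (length(kernel) != 1L || kernel < 1 || kernel %% 2 != 1)
    stop("'kernel' must be an odd integer >= 1", call. = FALSE)
  if (kernel == 1) return(img)
  round(.sepConvolve(img, .gaussianKernel1d(as.integer(kernel))))
}

#' Adaptive (local-mean) thresholding for dark nuclei
#'
#' A pixel becomes foreground iff its intensity is strictly below the mean
#' of the `wsize x wsize` window centred on it minus the offset `C` —
#' inverse polarity, because a nucleus is the darkest region within its
#' cytoplasm. The window mean is either the plain box mean or a
#' Gaussian-weighted mean; borders use reflect padding.
#'
#' @param img grayscale intensity matrix (at least `wsize` in each
#'   dimension).
#' @param wsize odd window side length, `3 <= wsize <= min(dim(img))`.
#' @param C offset subtracted from the local mean, in intensity levels.
#' @param meanType `"box"` (default) or `"gaussian"`.
#' @return a logical foreground mask of the same shape.
#' @examples
#' img <- matrix(200, 21, 21); img[9:13, 9:13] <- 50
#' sum(adaptiveThreshold(img, wsize = 21, C = 10))  # the dark block
#' @export
adaptiveThreshold <- function(img, wsize, C, meanType = c("box", "gaussian")) {
  meanType <- match.arg(meanType)
  stopifnot(is.matrix(img))
  if (length(wsize) != 1L || wsize < 3 || wsize %% 2 != 1)
    stop("'wsize' must be an odd integer >= 3", call. = FALSE)
  if (wsize > min(dim(img)))
    stop("'wsize' exceeds the image size", call. = FALSE)
  wsize <- as.integer(wsize)
  m <- if (meanType == "box") .localBoxMean(img, wsize)
       else .sepConvolve(img, .gaussianKernel1d(wsize))
  img < m - C
}
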