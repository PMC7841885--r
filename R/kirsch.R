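#' The eight Kirsch compass kernels
#'
#' The canonical Kirsch operator: a 3x3 kernel with three +5 coefficients
#' on one contiguous arc of the 8-neighbour ring and -3 elsewhere (centre
#' 0), rotated through the eight compass directions. Every kernel sums to
#' zero, so flat regions produce no response.
#'
#' @return a list of eight 3x3 integer matrices.
#' @examples
#' kirschMasks()[[1]]
#' @export
kirschMasks <- function() {
  # ring positions clockwise from the top-left corner
  ring <- rbind(c(1, 1), c(1, 2), c(1, 3), c(2, 3),
                c(3, 3), c(3, 2), c(3, 1), c(2, 1))
  lapply(0:7, function(k) {
    K <- matrix(-3L, 3L, 3L)
    K[2L, 2L] <- 0L
    pos <- ring[(k + 0:2) %% 8L + 1L, , drop = FALSE]
    K[pos] <- 5L
    K
  })
}

#' Eight-direction Kirsch compass-gradient magnitude
#'
#' Correlates the image with each of the eight compass kernels (reflect
#' padding at the borders), floors negative responses at zero, and keeps
#' the largest directional response per pixel. The response is zero on
#' constant regions and concentrates on intensity boundaries, which is
#' what lets the pipeline subtract irregular edge noise from the
#' thresholded mask.
#'
#' @param img grayscale intensity matrix, at least 3x3.
#' @return a numeric matrix of non-negative gradient magnitudes.
#' @examples
#' step <- cbind(matrix(0, 5, 3), matrix(100, 5, 3))
#' kirschResponse(step)
#' @export
kirschResponse <- function(img) {
  stopifnot(is.matrix(img))
  if (nrow(img) < 3L || ncol(img) < 3L)
    stop("image must be at least 3x3", call. = FALSE)
  nr <- nrow(img); nc <- ncol(img)
  p <- .padReflect(img, 1L)
  out <- matrix(0, nr, nc)
  for (K in kirschMasks()) {
    resp <- .correlate3x3(p, K, nr, nc)
    resp[resp < 0] <- 0
    out <- pmax(out, resp)
  }
  out
}

#' Threshold a gradient image into an edge map
#'
#' @param grad non-negative gradient magnitude matrix (from
#'   [kirschResponse()]).
#' @param threshold a pixel is an edge iff its gradient is `>= threshold`;
#'   must be `>= 0`, `Inf` yields an empty edge map.
#' @return a logical edge mask.
#' @export
edgeMask <- function(grad, threshold) {
  stopifnot(is.matrix(grad))
  if (length(threshold) != 1L || is.na(threshold) || threshold < 0)
    stop("'threshold' must be a scalar >= 0", call. = FALSE)
  grad >= threshold
}

#' Remove edge pixels from a foreground mask
#'
#' Binary set subtraction: `fg AND NOT edges`. Subtracting the compass
#' edge map erases irregularly shaped noise (whose response is strong
#' everywhere) while merely shrinking convex nucleus regions, whose lost
#' rim is restored later by [recoverAll()].
#'
#' @param fg,edges logical masks of identical shape.
#' @return a logical mask, always a subset of `fg`.
#' @export
subtractEdges <- function(fg, edges) {
  stopifnot(is.matrix(fg), is.matrix(edges))
  if (!identical(dim(fg), dim(edges)))
    stop("mask shapes differ", call. = FALSE)
  fg & !edges
}
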