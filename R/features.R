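# Contour shape descriptors. Solidity (contour area over convex hull
# area) and inertia ratio (minor over major equivalent-ellipse axis) are
# the two dimensionless descriptors used to reject non-nucleus contours.

# Count of integer pixel centres inside-or-on the convex hull of a pixel
# set. Coordinates are integers, so the half-plane cross products are
# exact in double precision; a tiny eps keeps on-edge points inside.
.hullPixelCount <- function(pixels) {
  n <- nrow(pixels)
  if (n <= 2L) return(n)
  x <- pixels[, 2L]; y <- pixels[, 1L]
  h <- grDevices::chull(x, y)
  if (length(h) < 3L) return(n)          # collinear set
  hx <- x[h]; hy <- y[h]
  area2 <- sum(hx * c(hy[-1L], hy[1L]) - c(hx[-1L], hx[1L]) * hy)
  if (abs(area2) < 1e-12) return(n)      # degenerate hull
  if (area2 < 0) { hx <- rev(hx); hy <- rev(hy) }  # force CCW
  cand <- expand.grid(row = min(y):max(y), col = min(x):max(x))
  cx <- cand$col; cy <- cand$row
  inside <- rep(TRUE, length(cx))
  nh <- length(hx)
  for (i in seq_len(nh)) {
    j <- if (i == nh) 1L else i + 1L
    cross <- (hx[j] - hx[i]) * (cy - hy[i]) - (hy[j] - hy[i]) * (cx - hx[i])
    inside <- inside & cross >= -1e-9
    if (!any(inside)) break
  }
  sum(inside)
}

#' Solidity of a pixel region
#'
#' The ratio of the region's area to its convex hull area, both measured
#' in pixels: hull area is the number of pixel centres lying inside or on
#' the convex hull of the region's pixel centres, so solidity is 1 for
#' every convex digitised shape and at most 1 always. Degenerate regions
#' (single pixel, collinear pixels) return 1 by convention.
#'
#' @param pixels an `n x 2` matrix of `(row, col)` pixel coordinates, or a
#'   region list as produced by [extractRegions()].
#' @return solidity in `(0, 1]`.
#' @examples
#' rect <- as.matrix(expand.grid(row = 1:4, col = 1:6))
#' regionSolidity(rect)  # 1
#' @export
regionSolidity <- function(pixels) {
  pixels <- .asPixels(pixels)
  n <- nrow(pixels)
  if (n == 0L) stop("empty region", call. = FALSE)
  n / .hullPixelCount(pixels)
}

#' Inertia ratio of a pixel region
#'
#' The minor-to-major axis length ratio of the region's equivalent
#' ellipse: `sqrt(lambda_min / lambda_max)` of the 2x2 second-central-
#' moment matrix of the pixel coordinates. 1 for rotationally symmetric
#' regions, near 0 for elongated ones. Regions with fewer than 2 pixels
#' (or a degenerate moment matrix) return 1 by convention.
#'
#' @inheritParams regionSolidity
#' @return inertia ratio in `[0, 1]`.
#' @examples
#' line <- cbind(row = rep(5, 50), col = 1:50)
#' regionInertiaRatio(line)  # 0: maximally elongated
#' @export
regionInertiaRatio <- function(pixels) {
  pixels <- .asPixels(pixels)
  n <- nrow(pixels)
  if (n < 2L) return(1)
  r <- pixels[, 1L] - mean(pixels[, 1L])
  c <- pixels[, 2L] - mean(pixels[, 2L])
  mu20 <- mean(r^2); mu02 <- mean(c^2); mu11 <- mean(r * c)
  half <- (mu20 + mu02) / 2
  d <- sqrt(((mu20 - mu02) / 2)^2 + mu11^2)
  lmax <- half + d; lmin <- half - d
  if (lmax < 1e-12) return(1)
  sqrt(max(lmin, 0) / lmax)
}

.asPixels <- function(x) {
  if (is.list(x) && !is.null(x$pixels)) x$pixels
  else if (is.matrix(x) && ncol(x) == 2L) x
  else stop("expected a region or an n x 2 coordinate matrix",
            call. = FALSE)
}

#' Contour features of candidate regions
#'
#' Computes, per region: `size` (boundary pixel count — the measure the
#' size filter operates on), `area` (filled pixel count), `solidity`,
#' `inertia_ratio` and `mean_intensity` over the source grayscale image.
#'
#' @param regions a list of regions from [extractRegions()] (or a single
#'   region).
#' @param img the grayscale intensity matrix the regions came from.
#' @return a `data.frame` with one row per region and columns `label`,
#'   `size`, `area`, `solidity`, `inertia_ratio`, `mean_intensity`.
#' @export
regionFeatures <- function(regions, img) {
  if (is.list(regions) && !is.null(regions$pixels)) regions <- list(regions)
  rows <- lapply(regions, function(reg) {
    px <- reg$pixels
    data.frame(
      label = reg$label,
      size = nrow(.regionBoundary(px)),
      area = nrow(px),
      solidity = regionSolidity(px),
      inertia_ratio = regionInertiaRatio(px),
      mean_intensity = mean(img[px])
    )
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Reject non-nucleus contours by shape
#'
#' Keeps exactly the regions with `minSize <= size <= maxSize`,
#' `solidity >= minSolidity` and `inertia_ratio >= minInertia`; order is
#' preserved. Nuclei are compact convex blobs, so low-solidity (ragged),
#' low-inertia (elongated), tiny or oversized contours are noise.
#'
#' @param regions list of regions from [extractRegions()].
#' @param img source grayscale matrix (for the feature table).
#' @param params a [NucleusParams-class] object.
#' @return the surviving regions, with the full feature table of the
#'   inputs attached as attribute `"features"`.
#' @export
filterRegions <- function(regions, img, params) {
  stopifnot(is(params, "NucleusParams"))
  if (!length(regions)) return(regions)
  ft <- regionFeatures(regions, img)
  keep <- ft$size >= params@minSize & ft$size <= params@maxSize &
    ft$solidity >= params@minSolidity &
    ft$inertia_ratio >= params@minInertia
  out <- regions[keep]
  attr(out, "features") <- cbind(ft, kept = keep)
  out
}
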