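#' Segment the nuclei of one cytology image
#'
#' Runs the four-stage pipeline: (1) grayscale conversion, Gaussian blur
#' and adaptive thresholding; (2) Kirsch compass-gradient edge map
#' subtraction (on the same blurred image); (3) contour extraction and
#' rejection by size/solidity/inertia ratio; (4) intensity-driven
#' recovery of each surviving region on the raw grayscale image. The
#' result is a pure function of the pixels and parameters: repeated runs
#' are bit-identical.
#'
#' @param img an intensity matrix or 3-channel array (see
#'   [toGrayscale()]).
#' @param params a [NucleusParams-class] object.
#' @return an integer label mask (0 = background, `1..K` nuclei), with
#'   per-stage region counts attached as attribute `"stageCounts"`
#'   (components after thresholding, after edge subtraction, regions
#'   kept by the filter, final instances).
#' @examples
#' fx <- generateCytology(syntheticSpec(seed = 3))
#' p <- nucleusParams(wsize = 35, C = 15, Irange = 25, minSolidity = 0.8,
#'                    minSize = 10, maxSize = 150, minInertia = 0.25)
#' mask <- segmentImage(fx$image, p)
#' attr(mask, "stageCounts")
#' @export
segmentImage <- function(img, params = nucleusParams()) {
  stopifnot(is(params, "NucleusParams"))
  validObject(params)
  g <- toGrayscale(img)
  if (nrow(g) < 3L || ncol(g) < 3L)
    stop("[preprocessing] image must be at least 3x3", call. = FALSE)
  b <- gaussianBlur(g, params@blurKernel)
  fg <- adaptiveThreshold(b, params@wsize, params@C, params@meanType)
  edges <- edgeMask(kirschResponse(b), params@kirschEdgeThreshold)
  m <- subtractEdges(fg, edges)
  regions <- extractRegions(m)
  kept <- filterRegions(regions, g, params)
  mask <- recoverAll(kept, g, params)
  nFg <- max(labelConnected(fg))
  structure(mask,
            stageCounts = c(thresholded = nFg,
                            afterEdgeSubtraction = length(regions),
                            afterFilter = length(kept),
                            recovered = max(mask)))
}

#' Segment a batch of image files
#'
#' Reads each file, segments it, and writes the label mask (16-bit TIFF,
#' same base name with suffix `_mask.tif`) and optionally a boundary
#' overlay PNG. Failures on individual files are recorded and the batch
#' continues.
#'
#' @param paths character vector of image file paths.
#' @param params a [NucleusParams-class] object.
#' @param outDir output directory (created if needed).
#' @param overlay also write `<base>_overlay.png` with nucleus
#'   boundaries marked.
#' @return a `data.frame` report: `file`, `status` (`"ok"` or the error
#'   message), `nInstances`, `seconds`.
#' @export
segmentBatch <- function(paths, params = nucleusParams(), outDir,
                         overlay = FALSE) {
  if (!length(paths))
    return(data.frame(file = character(), status = character(),
                      nInstances = integer(), seconds = numeric()))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(paths, function(path) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch({
      img <- readGrayImage(path)
      mask <- segmentImage(img, params)
      base <- tools::file_path_sans_ext(basename(path))
      writeLabelMask(mask, file.path(outDir, paste0(base, "_mask.tif")))
      if (overlay)
        png::writePNG(maskOverlay(img, mask),
                      file.path(outDir, paste0(base, "_overlay.png")))
      list(status = "ok", n = max(mask))
    }, error = function(e) list(status = conditionMessage(e), n = NA_integer_))
    data.frame(file = path, status = res$status, nInstances = res$n,
               seconds = proc.time()[["elapsed"]] - t0)
  })
  do.call(rbind, rows)
}

#' Colour overlay of nucleus boundaries on a grayscale image
#'
#' @param img grayscale intensity matrix in `[0, 255]`.
#' @param mask integer label mask of the same shape.
#' @param colour boundary colour as `(r, g, b)` in `[0, 1]`.
#' @return an `height x width x 3` array in `[0, 1]` suitable for
#'   [png::writePNG()].
#' @export
maskOverlay <- function(img, mask, colour = c(1, 1, 0)) {
  g <- toGrayscale(img) / 255
  stopifnot(identical(dim(g), dim(mask)))
  out <- array(rep(g, 3L), dim = c(dim(g), 3L))
  for (reg in .maskRegionPixels(mask)) {
    bd <- .regionBoundary(reg)
    for (ch in 1:3)
      out[cbind(bd, ch)] <- colour[ch]
  }
  out
}
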