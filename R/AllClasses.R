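#' Tunable parameters of the nucleus segmentation pipeline
#'
#' Holds the seven tunable parameters of the segmentation algorithm
#' (adaptive-threshold window size and offset, recovery intensity range,
#' minimum solidity, minimum/maximum contour size, minimum inertia ratio)
#' together with the fixed constants of the method (recovery stopping
#' solidity 0.75, true-positive Dice gate 0.6) and the preprocessing knobs
#' (Gaussian blur kernel, Kirsch edge threshold, local-mean type).
#'
#' @slot wsize adaptive-threshold window side length in pixels; odd, >= 3.
#' @slot C adaptive-threshold offset subtracted from the local mean,
#'   in intensity levels.
#' @slot Irange allowed difference between a candidate pixel's intensity and
#'   the running mean intensity of a region during recovery, in levels.
#' @slot minSolidity minimum contour solidity accepted by the shape filter,
#'   in (0, 1].
#' @slot minSize,maxSize accepted contour size range; size is the boundary
#'   pixel count (see [regionFeatures()]); 0 < minSize < maxSize.
#' @slot minInertia minimum inertia ratio (minor/major equivalent-ellipse
#'   axis), in [0, 1].
#' @slot recoverySolidity solidity below which region growth stops; fixed
#'   default 0.75.
#' @slot diceThreshold per-nucleus Dice value at or above which a detection
#'   counts as a true positive; fixed default 0.6.
#' @slot kirschEdgeThreshold gradient magnitude at or above which a pixel is
#'   declared an edge; `Inf` disables the edge-subtraction stage.
#' @slot blurKernel Gaussian smoothing kernel side length in pixels; odd,
#'   >= 1 (1 disables smoothing).
#' @slot meanType `"box"` for the plain window mean, `"gaussian"` for a
#'   Gaussian-weighted window mean.
#'
#' @seealso [nucleusParams()], [readParams()]
#' @export
setClass("NucleusParams",
  representation(
    wsize = "numeric",
    C = "numeric",
    Irange = "numeric",
    minSolidity = "numeric",
    minSize = "numeric",
    maxSize = "numeric",
    minInertia = "numeric",
    recoverySolidity = "numeric",
    diceThreshold = "numeric",
    kirschEdgeThreshold = "numeric",
    blurKernel = "numeric",
    meanType = "character"
  ),
  prototype(
    wsize = 55, C = 40, Irange = 30, minSolidity = 0.8,
    minSize = 20, maxSize = 140, minInertia = 0.4,
    recoverySolidity = 0.75, diceThreshold = 0.6,
    kirschEdgeThreshold = 255, blurKernel = 5, meanType = "box"
  )
)

setValidity("NucleusParams", function(object) {
  msg <- character()
  scal <- function(x) length(x) == 1L && is.finite(x)
  if (!scal(object@wsize) || object@wsize < 3 || object@wsize %% 2 != 1)
    msg <- c(msg, "'wsize' must be an odd scalar >= 3")
  if (length(object@C) != 1L || !is.finite(object@C))
    msg <- c(msg, "'C' must be a finite scalar")
  if (!scal(object@Irange) || object@Irange < 0)
    msg <- c(msg, "'Irange' must be >= 0")
  if (!scal(object@minSolidity) || object@minSolidity <= 0 ||
      object@minSolidity > 1)
    msg <- c(msg, "'minSolidity' must be in (0, 1]")
  if (!scal(object@minSize) || !scal(object@maxSize) ||
      object@minSize <= 0 || object@minSize >= object@maxSize)
    msg <- c(msg, "need 0 < minSize < maxSize")
  if (!scal(object@minInertia) || object@minInertia < 0 ||
      object@minInertia > 1)
    msg <- c(msg, "'minInertia' must be in [0, 1]")
  if (!scal(object@recoverySolidity) || object@recoverySolidity <= 0 ||
      object@recoverySolidity >= 1)
    msg <- c(msg, "'recoverySolidity' must be in (0, 1)")
  if (!scal(object@diceThreshold) || object@diceThreshold <= 0 ||
      object@diceThreshold > 1)
    msg <- c(msg, "'diceThreshold' must be in (0, 1]")
  if (length(object@kirschEdgeThreshold) != 1L ||
      is.na(object@kirschEdgeThreshold) || object@kirschEdgeThreshold < 0)
    msg <- c(msg, "'kirschEdgeThreshold' must be >= 0 (Inf allowed)")
  if (!scal(object@blurKernel) || object@blurKernel < 1 ||
      object@blurKernel %% 2 != 1)
    msg <- c(msg, "'blurKernel' must be an odd scalar >= 1")
  if (length(object@meanType) != 1L ||
      !object@meanType %in% c("box", "gaussian"))
    msg <- c(msg, "'meanType' must be \"box\" or \"gaussian\"")
  if (length(msg)) msg else TRUE
})

#' Object-level evaluation of a segmentation against ground truth
#'
#' Produced by [evaluateMasks()] and [evaluateBatch()]. Stores the matched
#' true/false positive and false negative counts under the Dice gate, the
#' per-nucleus Dice values of matched pairs, and the derived object-level
#' scores.
#'
#' @slot TP,FP,FN matched instance counts.
#' @slot perNucleusDice Dice values of greedily matched (ground truth,
#'   prediction) pairs, in ground-truth label order.
#' @slot precision,recall,f1 object-level scores; `NaN` when undefined
#'   (no predictions / no ground-truth instances).
#' @slot aji Aggregated Jaccard Index; `NA` when not computed.
#' @slot nImages number of images pooled into this result.
#'
#' @seealso [evaluateMasks()], [matchInstances()], [aggregatedJaccard()]
#' @export
setClass("NucleusEvaluation",
  representation(
    TP = "integer", FP = "integer", FN = "integer",
    perNucleusDice = "numeric",
    precision = "numeric", recall = "numeric", f1 = "numeric",
    aji = "numeric", nImages = "integer"
  ),
  prototype(TP = 0L, FP = 0L, FN = 0L, perNucleusDice = numeric(),
            precision = NaN, recall = NaN, f1 = NaN, aji = NA_real_,
            nImages = 1L)
)

setValidity("NucleusEvaluation", function(object) {
  msg <- character()
  if (object@TP < 0L || object@FP < 0L || object@FN < 0L)
    msg <- c(msg, "counts must be non-negative")
  if (any(object@perNucleusDice < 0 | object@perNucleusDice > 1, na.rm = TRUE))
    msg <- c(msg, "per-nucleus Dice values must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})
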