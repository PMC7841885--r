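#' @name evaluation-accessors
#' @title Accessors for NucleusEvaluation objects
#' @description Extract the object-level scores and matched counts from a
#'   [NucleusEvaluation-class] object.
#' @param x a `NucleusEvaluation` object.
#' @return `precision`, `recall`, `f1score` and `ajiScore` return a single
#'   numeric value (`NaN`/`NA` when undefined); `matchCounts` a named integer
#'   vector with elements `TP`, `FP`, `FN`; `nucleusDice` the numeric vector
#'   of matched per-nucleus Dice values.
#' @examples
#' gt <- matrix(0L, 8, 8); gt[2:4, 2:4] <- 1L
#' ev <- evaluateMasks(gt, gt)
#' precision(ev); recall(ev); f1score(ev)
NULL

#' @rdname evaluation-accessors
#' @export
setGeneric("precision", function(x) standardGeneric("precision"))

#' @rdname evaluation-accessors
#' @export
setGeneric("recall", function(x) standardGeneric("recall"))

#' @rdname evaluation-accessors
#' @export
setGeneric("f1score", function(x) standardGeneric("f1score"))

#' @rdname evaluation-accessors
#' @export
setGeneric("ajiScore", function(x) standardGeneric("ajiScore"))

#' @rdname evaluation-accessors
#' @export
setGeneric("matchCounts", function(x) standardGeneric("matchCounts"))

#' @rdname evaluation-accessors
#' @export
setGeneric("nucleusDice", function(x) standardGeneric("nucleusDice"))

#' @rdname evaluation-accessors
setMethod("precision", "NucleusEvaluation", function(x) x@precision)

#' @rdname evaluation-accessors
setMethod("recall", "NucleusEvaluation", function(x) x@recall)

#' @rdname evaluation-accessors
setMethod("f1score", "NucleusEvaluation", function(x) x@f1)

#' @rdname evaluation-accessors
setMethod("ajiScore", "NucleusEvaluation", function(x) x@aji)

#' @rdname evaluation-accessors
setMethod("matchCounts", "NucleusEvaluation",
          function(x) c(TP = x@TP, FP = x@FP, FN = x@FN))

#' @rdname evaluation-accessors
setMethod("nucleusDice", "NucleusEvaluation", function(x) x@perNucleusDice)

setMethod("show", "NucleusEvaluation", function(object) {
  cat("NucleusEvaluation (", object@nImages, " image",
      if (object@nImages != 1L) "s", ")\n", sep = "")
  cat(sprintf("  TP = %d, FP = %d, FN = %d\n",
              object@TP, object@FP, object@FN))
  cat(sprintf("  precision = %.3f  recall = %.3f  F1 = %.3f\n",
              object@precision, object@recall, object@f1))
  if (!is.na(object@aji)) cat(sprintf("  AJI = %.3f\n", object@aji))
  invisible(object)
})

setMethod("show", "NucleusParams", function(object) {
  cat("NucleusParams\n")
  cat(sprintf("  wsize = %g, C = %g, Irange = %g\n",
              object@wsize, object@C, object@Irange))
  cat(sprintf("  MinSolid = %g, MinSize = %g, MaxSize = %g, MinInertia = %g\n",
              object@minSolidity, object@minSize, object@maxSize,
              object@minInertia))
  cat(sprintf(
    "  recovery solidity = %g, Dice gate = %g, edge threshold = %g\n",
    object@recoverySolidity, object@diceThreshold,
    object@kirschEdgeThreshold))
  cat(sprintf("  blur kernel = %g, mean type = %s\n",
              object@blurKernel, object@meanType))
  invisible(object)
})
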