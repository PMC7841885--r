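# Evaluation protocol: per-nucleus Dice with a 0.6 true-positive gate,
# object-level precision/recall/F1, and the Aggregated Jaccard Index.

# Re-index labels to a contiguous 1..K (ascending original label order).
.relabel <- function(lab) {
  stopifnot(is.matrix(lab))
  lab <- matrix(as.integer(round(lab)), nrow(lab), ncol(lab))
  if (any(lab < 0L)) stop("negative labels", call. = FALSE)
  u <- sort(unique(lab[lab > 0L]))
  if (length(u) && !identical(u, seq_along(u))) {
    map <- integer(max(u)); map[u] <- seq_along(u)
    lab[lab > 0L] <- map[lab[lab > 0L]]
  }
  lab
}

# Pairwise overlap table between two label masks: one row per
# (gt, pred) pair with a non-empty intersection.
.overlapTable <- function(gt, pred) {
  nG <- max(gt); nP <- max(pred)
  sel <- gt > 0L & pred > 0L
  if (!any(sel) || nP == 0L)
    return(data.frame(g = integer(), p = integer(), inter = integer()))
  key <- (gt[sel] - 1L) * nP + pred[sel]
  cnt <- tabulate(key, nbins = nG * nP)
  nz <- which(cnt > 0L)
  data.frame(g = ((nz - 1L) %/% nP) + 1L,
             p = ((nz - 1L) %% nP) + 1L,
             inter = cnt[nz])
}

#' Dice coefficient between two pixel sets
#'
#' `2|A n B| / (|A| + |B|)`: 1 for identical non-empty sets, 0 for
#' disjoint ones. Undefined (an error) when both sets are empty.
#'
#' @param A,B logical masks of identical shape.
#' @return Dice similarity in `[0, 1]`.
#' @examples
#' a <- matrix(FALSE, 4, 4); a[1:2, 1:2] <- TRUE
#' b <- matrix(FALSE, 4, 4); b[2:3, 1:2] <- TRUE
#' diceCoefficient(a, b)  # overlap 2 of 4+4 -> 0.5
#' @export
diceCoefficient <- function(A, B) {
  stopifnot(is.matrix(A), is.matrix(B), identical(dim(A), dim(B)))
  nA <- sum(A); nB <- sum(B)
  if (nA + nB == 0L) stop("Dice undefined: both sets empty", call. = FALSE)
  2 * sum(A & B) / (nA + nB)
}

#' Match predicted against ground-truth nuclei under the Dice gate
#'
#' Overlapping (ground truth, prediction) pairs are matched greedily
#' one-to-one by descending Dice (ties broken by ground-truth then
#' predicted label). A matched pair with Dice at or above
#' `diceThreshold` is a true positive; predictions unmatched or matched
#' below the gate are false positives; ground-truth nuclei without a
#' qualifying match are false negatives. Consequently
#' `TP + FN = #ground truth` and `TP + FP = #predictions`.
#'
#' @param gt,pred integer label masks of identical shape (labels are
#'   re-indexed to `1..K` internally).
#' @param diceThreshold the true-positive gate, default 0.6.
#' @return a list with `TP`, `FP`, `FN`, `perNucleusDice` (Dice of
#'   matched pairs in ground-truth label order) and the pair table
#'   `matches`.
#' @export
matchInstances <- function(gt, pred, diceThreshold = 0.6) {
  if (!identical(dim(gt), dim(pred)))
    stop("mask shapes differ", call. = FALSE)
  gt <- .relabel(gt); pred <- .relabel(pred)
  nG <- max(gt); nP <- max(pred)
  aG <- tabulate(gt[gt > 0L], nbins = nG)
  aP <- tabulate(pred[pred > 0L], nbins = nP)
  ov <- .overlapTable(gt, pred)
  ov$dice <- 2 * ov$inter / (aG[ov$g] + aP[ov$p])
  ov <- ov[order(-ov$dice, ov$g, ov$p), , drop = FALSE]
  gUsed <- logical(nG); pUsed <- logical(nP)
  matched <- ov[0, ]
  for (i in seq_len(nrow(ov))) {
    g <- ov$g[i]; p <- ov$p[i]
    if (!gUsed[g] && !pUsed[p]) {
      gUsed[g] <- TRUE; pUsed[p] <- TRUE
      matched <- rbind(matched, ov[i, ])
    }
  }
  matched <- matched[order(matched$g), , drop = FALSE]
  TP <- sum(matched$dice >= diceThreshold)
  list(TP = as.integer(TP),
       FP = as.integer(nP - TP),
       FN = as.integer(nG - TP),
       perNucleusDice = matched$dice,
       matches = matched)
}

#' Object-level precision, recall and F1 from matched counts
#'
#' `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`, and F1 their harmonic
#' mean. When a denominator is zero the corresponding score is `NaN`
#' (undefined) with a warning.
#'
#' @param TP,FP,FN non-negative counts.
#' @return named numeric vector `c(precision, recall, f1)`.
#' @examples
#' prfScores(TP = 14, FP = 1, FN = 2)
#' @export
prfScores <- function(TP, FP, FN) {
  stopifnot(TP >= 0, FP >= 0, FN >= 0)
  p <- if (TP + FP > 0) TP / (TP + FP) else NaN
  r <- if (TP + FN > 0) TP / (TP + FN) else NaN
  if (is.nan(p) || is.nan(r))
    warning("undefined metric: no predictions and/or no ground truth",
            call. = FALSE)
  c(precision = p, recall = r, f1 = f1Score(p, r))
}

#' Harmonic mean of precision and recall
#'
#' @param precision,recall scores in `[0, 1]`.
#' @return `2 / (1/precision + 1/recall)`; 0 when both are 0, `NaN` if
#'   either is `NaN`.
#' @examples
#' f1Score(0.978, 0.933)
#' @export
f1Score <- function(precision, recall) {
  if (is.nan(precision) || is.nan(recall)) return(NaN)
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

# AJI numerator/denominator accumulation for one mask pair, so image
# sets can be pooled before the final ratio.
.ajiParts <- function(gt, pred) {
  gt <- .relabel(gt); pred <- .relabel(pred)
  nG <- max(gt); nP <- max(pred)
  if (nG == 0L)
    stop("AJI undefined: ground truth has no instances", call. = FALSE)
  aG <- tabulate(gt[gt > 0L], nbins = nG)
  aP <- tabulate(pred[pred > 0L], nbins = nP)
  ov <- .overlapTable(gt, pred)
  ov$jac <- ov$inter / (aG[ov$g] + aP[ov$p] - ov$inter)
  used <- logical(nP)
  num <- 0; den <- 0
  for (g in seq_len(nG)) {
    cand <- ov[ov$g == g & !used[ov$p], , drop = FALSE]
    if (nrow(cand)) {
      best <- cand[order(-cand$jac, cand$p)[1L], ]
      used[best$p] <- TRUE
      num <- num + best$inter
      den <- den + aG[g] + aP[best$p] - best$inter
    } else {
      den <- den + aG[g]
    }
  }
  den <- den + sum(aP[!used])
  c(num = num, den = den)
}

#' Aggregated Jaccard Index between two instance label masks
#'
#' For each ground-truth instance (ascending label) the unused predicted
#' instance maximising the Jaccard overlap is selected (ties to the
#' lowest predicted label) and consumed; intersections accumulate in the
#' numerator, unions in the denominator, and the pixels of predictions
#' never selected are added to the denominator. Combines pixel-level and
#' object-level agreement in one measure in `[0, 1]`.
#'
#' @param gt,pred integer label masks of identical shape; `gt` must
#'   contain at least one instance.
#' @return the AJI value.
#' @export
aggregatedJaccard <- function(gt, pred) {
  if (!identical(dim(gt), dim(pred)))
    stop("mask shapes differ", call. = FALSE)
  parts <- .ajiParts(gt, pred)
  unname(parts["num"] / parts["den"])
}

#' Evaluate one predicted label mask against ground truth
#'
#' @param gt,pred integer label masks of identical shape.
#' @param diceThreshold true-positive Dice gate (default 0.6).
#' @param computeAji also compute the Aggregated Jaccard Index (skipped
#'   and set to `NA` when the ground truth is empty).
#' @return a [NucleusEvaluation-class] object.
#' @examples
#' gt <- matrix(0L, 16, 16); gt[3:8, 3:8] <- 1L; gt[11:14, 10:14] <- 2L
#' evaluateMasks(gt, gt)
#' @export
evaluateMasks <- function(gt, pred, diceThreshold = 0.6, computeAji = TRUE) {
  m <- matchInstances(gt, pred, diceThreshold)
  sc <- suppressWarnings(prfScores(m$TP, m$FP, m$FN))
  aji <- if (computeAji && max(gt) > 0) aggregatedJaccard(gt, pred)
         else NA_real_
  new("NucleusEvaluation", TP = m$TP, FP = m$FP, FN = m$FN,
      perNucleusDice = m$perNucleusDice,
      precision = unname(sc["precision"]), recall = unname(sc["recall"]),
      f1 = unname(sc["f1"]), aji = aji, nImages = 1L)
}

#' Evaluate an image set, per image and pooled
#'
#' Counts are pooled (micro-averaged) across images: TP/FP/FN are summed
#' before computing precision/recall/F1, and the AJI numerator and
#' denominator are accumulated across images before the final ratio.
#'
#' @param gts,preds lists of label masks, paired by position.
#' @param diceThreshold true-positive Dice gate (default 0.6).
#' @param computeAji also compute AJI (default `TRUE`).
#' @return a list with `perImage` (a `data.frame`) and `pooled`
#'   (a [NucleusEvaluation-class] object).
#' @export
evaluateBatch <- function(gts, preds, diceThreshold = 0.6,
                          computeAji = TRUE) {
  stopifnot(length(gts) == length(preds), length(gts) >= 1L)
  rows <- vector("list", length(gts))
  TP <- FP <- FN <- 0L
  ajiNum <- ajiDen <- 0
  allDice <- numeric()
  for (i in seq_along(gts)) {
    m <- matchInstances(gts[[i]], preds[[i]], diceThreshold)
    sc <- suppressWarnings(prfScores(m$TP, m$FP, m$FN))
    aji_i <- NA_real_
    if (computeAji && max(gts[[i]]) > 0) {
      parts <- .ajiParts(gts[[i]], preds[[i]])
      ajiNum <- ajiNum + parts["num"]; ajiDen <- ajiDen + parts["den"]
      aji_i <- unname(parts["num"] / parts["den"])
    }
    TP <- TP + m$TP; FP <- FP + m$FP; FN <- FN + m$FN
    allDice <- c(allDice, m$perNucleusDice)
    rows[[i]] <- data.frame(image = i, TP = m$TP, FP = m$FP, FN = m$FN,
                            precision = unname(sc["precision"]),
                            recall = unname(sc["recall"]),
                            f1 = unname(sc["f1"]), aji = aji_i)
  }
  sc <- suppressWarnings(prfScores(TP, FP, FN))
  pooled <- new("NucleusEvaluation", TP = TP, FP = FP, FN = FN,
                perNucleusDice = allDice,
                precision = unname(sc["precision"]),
                recall = unname(sc["recall"]), f1 = unname(sc["f1"]),
                aji = if (computeAji && ajiDen > 0)
                        unname(ajiNum / ajiDen) else NA_real_,
                nImages = length(gts))
  list(perImage = do.call(rbind, rows), pooled = pooled)
}
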