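#' Candidate value grid for the seven tunable parameters
#'
#' The default lists bracket the published per-dataset settings; any
#' subset of the seven names can be overridden, and unnamed parameters
#' fall back to a single default candidate taken from `params`.
#'
#' @param wsize,C,Irange,MinSolid,MinSize,MaxSize,MinInertia numeric
#'   vectors of candidate values (published external names).
#' @return a named list of candidate vectors.
#' @examples
#' parameterGrid(wsize = c(25, 35), C = c(10, 20))
#' @export
parameterGrid <- function(wsize = c(35, 41, 55), C = c(40, 48, 50),
                          Irange = c(30, 40), MinSolid = c(0.6, 0.8, 0.85),
                          MinSize = c(5, 20), MaxSize = c(50, 70, 140),
                          MinInertia = c(0.2, 0.3, 0.4)) {
  list(wsize = wsize, C = C, Irange = Irange, MinSolid = MinSolid,
       MinSize = MinSize, MaxSize = MaxSize, MinInertia = MinInertia)
}

#' Grid-search the tunable parameters on an annotated training set
#'
#' Runs the full segmentation pipeline for every combination in the
#' Cartesian product of the grid, scores it against the training ground
#' truth with pooled (micro-averaged) metrics, and returns the argmax of
#' the chosen measure. Ties are broken by the earliest combination in
#' enumeration order (first grid field varying fastest). A small
#' annotated set (around 10 images) is typically sufficient; note there
#' is no validation split, so the selected values can overfit a tiny
#' training set.
#'
#' @param images list of grayscale intensity matrices (or RGB arrays).
#' @param gts list of ground-truth label masks, paired by position.
#' @param grid a candidate grid from [parameterGrid()].
#' @param metric one of `"f1"`, `"precision"`, `"recall"`, `"aji"`.
#' @param params base [NucleusParams-class] supplying the fields not in
#'   the grid.
#' @param verbose print per-combination progress.
#' @return a list with `params` (best [NucleusParams-class]), `score`,
#'   `metric`, and `results` — the full audit table with one row per
#'   combination and its pooled precision/recall/F1/AJI.
#' @export
gridSearch <- function(images, gts, grid = parameterGrid(),
                       metric = c("f1", "precision", "recall", "aji"),
                       params = nucleusParams(), verbose = FALSE) {
  metric <- match.arg(metric)
  stopifnot(length(images) == length(gts))
  if (!length(images)) stop("empty training set", call. = FALSE)
  if (!length(grid) || !all(lengths(grid) >= 1L))
    stop("empty parameter grid", call. = FALSE)
  combos <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  scoreCol <- c(f1 = "f1", precision = "precision", recall = "recall",
                aji = "aji")[[metric]]
  results <- combos
  results$precision <- results$recall <- results$f1 <- results$aji <-
    NA_real_
  best <- list(score = -Inf, params = NULL)
  for (i in seq_len(nrow(combos))) {
    p <- updateParams(params, as.list(combos[i, , drop = FALSE]))
    preds <- lapply(images, segmentImage, params = p)
    ev <- evaluateBatch(gts, preds, diceThreshold = p@diceThreshold,
                        computeAji = (metric == "aji"))
    pooled <- ev$pooled
    results$precision[i] <- pooled@precision
    results$recall[i] <- pooled@recall
    results$f1[i] <- pooled@f1
    results$aji[i] <- pooled@aji
    s <- results[[scoreCol]][i]
    if (verbose)
      message(sprintf("combo %d/%d: %s = %.4f", i, nrow(combos),
                      metric, s))
    if (is.finite(s) && s > best$score)
      best <- list(score = s, params = p)
  }
  if (is.null(best$params))
    stop("no grid combination produced a defined '", metric, "' score",
         call. = FALSE)
  list(params = best$params, score = best$score, metric = metric,
       results = results)
}
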