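# Stage 4: nucleus size recovery. The edge-subtraction stage shrinks true
# nuclei; each surviving region is re-grown by admitting 8-neighbourhood
# pixels whose intensity lies within Irange of the region's running mean
# intensity, measured on the raw (unblurred) grayscale image.

# Fixed neighbour visiting order (row-major) for deterministic growth.
.nbOffsets <- rbind(c(-1L, -1L), c(-1L, 0L), c(-1L, 1L), c(0L, -1L),
                    c(0L, 1L), c(1L, -1L), c(1L, 0L), c(1L, 1L))

.boundaryCountM <- function(member, r0, r1, c0, c1) {
  nrow(.regionBoundary(.whichPixels(member, r0, r1, c0, c1)))
}

.whichPixels <- function(member, r0, r1, c0, c1) {
  sub <- member[r0:r1, c0:c1, drop = FALSE]
  w <- which(sub, arr.ind = TRUE)
  cbind(row = w[, 1L] + r0 - 1L, col = w[, 2L] + c0 - 1L)
}

#' Grow one nucleus region by running-mean intensity admission
#'
#' Candidate pixels (the 8-neighbourhood of the region, enqueued from the
#' boundary pixels in raster order, FIFO) are examined one by one: a pixel
#' is admitted iff its intensity differs from the region's running mean by
#' at most `Irange`; the mean is updated after every admission and each
#' candidate is examined once. Growth stops when (1) the queue is
#' exhausted, (2) the region size (boundary pixel count) exceeds
#' `maxSize`, or (3) the region's solidity drops below
#' `recoverySolidity`; conditions 2-3 are checked after every admission
#' (and once before any) and return the region as it stands, guarding
#' against runaway growth in low-contrast images.
#'
#' @param region a region list (`label`, `pixels`) that passed
#'   [filterRegions()].
#' @param img the raw grayscale intensity matrix.
#' @param params a [NucleusParams-class] object (`Irange`, `maxSize`,
#'   `recoverySolidity`).
#' @param claimed optional logical matrix of pixels owned by other
#'   regions; such pixels are never admitted.
#' @return the grown region (a superset of the input), pixels in raster
#'   order.
#' @export
growRegion <- function(region, img, params, claimed = NULL) {
  stopifnot(is(params, "NucleusParams"), is.matrix(img))
  nr <- nrow(img); nc <- ncol(img)
  px <- region$pixels
  member <- matrix(FALSE, nr, nc)
  member[px] <- TRUE
  if (is.null(claimed)) claimed <- matrix(FALSE, nr, nc)
  r0 <- min(px[, 1L]); r1 <- max(px[, 1L])
  c0 <- min(px[, 2L]); c1 <- max(px[, 2L])

  finish <- function() {
    out <- region
    out$pixels <- .whichPixels(member, r0, r1, c0, c1)
    out$pixels <- out$pixels[order(out$pixels[, 1L], out$pixels[, 2L]), ,
                             drop = FALSE]
    out
  }

  # stopping conditions may already hold before any admission
  if (.boundaryCountM(member, r0, r1, c0, c1) > params@maxSize ||
      regionSolidity(px) < params@recoverySolidity)
    return(finish())

  S <- sum(img[px]); n <- nrow(px)
  seen <- member | claimed
  cap <- 256L
  qr <- integer(cap); qc <- integer(cap); head <- 1L; tail <- 0L
  push <- function(pr, pc) {
    keep <- pr >= 1L & pr <= nr & pc >= 1L & pc <= nc
    pr <- pr[keep]; pc <- pc[keep]
    if (!length(pr)) return(invisible())
    fresh <- !seen[cbind(pr, pc)]
    pr <- pr[fresh]; pc <- pc[fresh]
    if (!length(pr)) return(invisible())
    seen[cbind(pr, pc)] <<- TRUE
    while (tail + length(pr) > cap) {
      cap <<- cap * 2L
      length(qr) <<- cap; length(qc) <<- cap
    }
    qr[tail + seq_along(pr)] <<- pr
    qc[tail + seq_along(pc)] <<- pc
    tail <<- tail + length(pr)
    invisible()
  }

  bd <- .regionBoundary(px)
  for (i in seq_len(nrow(bd)))
    push(bd[i, 1L] + .nbOffsets[, 1L], bd[i, 2L] + .nbOffsets[, 2L])

  while (head <= tail) {
    pr <- qr[head]; pc <- qc[head]; head <- head + 1L
    if (abs(img[pr, pc] - S / n) > params@Irange) next
    member[pr, pc] <- TRUE
    S <- S + img[pr, pc]; n <- n + 1L
    r0 <- min(r0, pr); r1 <- max(r1, pr)
    c0 <- min(c0, pc); c1 <- max(c1, pc)
    curPx <- .whichPixels(member, r0, r1, c0, c1)
    if (nrow(.regionBoundary(curPx)) > params@maxSize) break
    if (regionSolidity(curPx) < params@recoverySolidity) break
    push(pr + .nbOffsets[, 1L], pc + .nbOffsets[, 2L])
  }
  finish()
}

#' Recover all filtered regions into a label mask
#'
#' Applies [growRegion()] to each region in label order. Every seed pixel
#' is pre-claimed, and each grown pixel is claimed as it is assigned, so
#' regions stay pairwise disjoint: the first region to reach a contested
#' pixel keeps it, and processing order makes the outcome deterministic.
#' Output labels are `1..K` in processing order.
#'
#' @param regions pairwise-disjoint regions that passed
#'   [filterRegions()].
#' @param img the raw grayscale intensity matrix.
#' @param params a [NucleusParams-class] object.
#' @return an integer label mask (0 = background).
#' @export
recoverAll <- function(regions, img, params) {
  stopifnot(is(params, "NucleusParams"), is.matrix(img))
  out <- matrix(0L, nrow(img), ncol(img))
  if (!length(regions)) return(out)
  allPx <- do.call(rbind, lapply(regions, `[[`, "pixels"))
  claimed <- matrix(FALSE, nrow(img), ncol(img))
  claimed[allPx] <- TRUE
  if (sum(claimed) != nrow(allPx))
    stop("input regions overlap", call. = FALSE)
  for (k in seq_along(regions)) {
    reg <- regions[[k]]
    mine <- claimed
    mine[reg$pixels] <- FALSE
    grown <- growRegion(reg, img, params, claimed = mine)
    claimed[grown$pixels] <- TRUE
    out[grown$pixels] <- k
  }
  out
}
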