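# Connected-component machinery. Foreground components are 8-connected
# (diagonal contact joins regions), matching contour-following conventions
# for dark-blob extraction; the complement uses 4-connectivity, the
# topologically consistent dual, for hole detection.

#' Label connected components of a binary mask
#'
#' Components are labelled `1..K` in raster-scan order (row by row, left
#' to right) of each component's first-encountered pixel, which makes all
#' downstream per-region processing deterministic.
#'
#' @param mask logical matrix.
#' @param connectivity 8 (default) or 4.
#' @return an integer matrix; 0 = background.
#' @examples
#' m <- matrix(FALSE, 4, 4); m[1, 1] <- TRUE; m[2, 2] <- TRUE; m[4, 4] <- TRUE
#' labelConnected(m)  # the diagonal pair is one component
#' @export
labelConnected <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask), is.logical(mask))
  connectivity <- match.arg(as.character(connectivity), c("8", "4"))
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  idx <- which(mask)
  if (!length(idx)) return(lab)
  r <- ((idx - 1L) %% nr) + 1L
  c <- ((idx - 1L) %/% nr) + 1L
  vmap <- integer(nr * nc)
  vmap[idx] <- seq_along(idx)
  offs <- if (connectivity == "8")
    list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))
  else list(c(0L, 1L), c(1L, 0L))
  edges <- integer(0)
  for (o in offs) {
    r2 <- r + o[1L]; c2 <- c + o[2L]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    if (!any(ok)) next
    nidx <- (c2[ok] - 1L) * nr + r2[ok]
    hit <- vmap[nidx] > 0L
    if (any(hit))
      edges <- c(edges, rbind(vmap[idx[ok]][hit], vmap[nidx][hit]))
  }
  g <- igraph::make_graph(edges, n = length(idx), directed = FALSE)
  memb <- igraph::components(g)$membership
  # relabel components by raster order (row-major) of their first pixel
  key <- (r - 1L) * nc + c
  firstKey <- tapply(key, memb, min)
  newLab <- integer(length(firstKey))
  newLab[order(firstKey)] <- seq_along(firstKey)
  lab[idx] <- newLab[memb]
  lab
}

#' Fill enclosed holes in a binary mask
#'
#' Background components (4-connected) that do not touch the image border
#' are holes and become foreground. Hollow candidate regions (e.g. a
#' nucleus whose centre survived thresholding as a ring) are thereby
#' solidified before any contour feature is computed.
#'
#' @param mask logical matrix.
#' @return a logical matrix, a superset of `mask`.
#' @export
fillHoles <- function(mask) {
  stopifnot(is.matrix(mask), is.logical(mask))
  bg <- labelConnected(!mask, connectivity = 4)
  border <- unique(c(bg[1L, ], bg[nrow(bg), ], bg[, 1L], bg[, ncol(bg)]))
  mask | (bg > 0L & !(bg %in% border))
}

# Raster-ordered (row, col) coordinates of the pixels of each label.
.maskRegionPixels <- function(lab) {
  idx <- which(lab > 0L)
  if (!length(idx)) return(list())
  nr <- nrow(lab)
  r <- ((idx - 1L) %% nr) + 1L
  c <- ((idx - 1L) %/% nr) + 1L
  labs <- lab[idx]
  out <- lapply(split(seq_along(idx), labs), function(i) {
    o <- order(r[i], c[i])
    cbind(row = r[i][o], col = c[i][o])
  })
  unname(out[order(as.integer(names(out)))])
}

#' Extract candidate nucleus regions from a binary mask
#'
#' One region per 8-connected foreground component, after hole filling,
#' in deterministic raster-scan label order. Each region is a list with
#' elements `label` (integer) and `pixels` (an `n x 2` matrix of
#' `(row, col)` coordinates in raster order).
#'
#' @param mask logical matrix.
#' @param fill fill enclosed holes first (default `TRUE`).
#' @return a list of regions (empty list for an empty mask).
#' @examples
#' m <- matrix(FALSE, 9, 9); m[2:4, 2:4] <- TRUE; m[6:8, 6:8] <- TRUE
#' length(extractRegions(m))
#' @export
extractRegions <- function(mask, fill = TRUE) {
  if (fill) mask <- fillHoles(mask)
  lab <- labelConnected(mask, connectivity = 8)
  px <- .maskRegionPixels(lab)
  mapply(function(p, l) list(label = l, pixels = p),
         px, seq_along(px), SIMPLIFY = FALSE)
}

# Boundary pixels of a region: members with fewer than 8 member
# neighbours (image-border pixels count as boundary). Returns (row, col)
# coordinates in raster order.
.regionBoundary <- function(pixels) {
  n <- nrow(pixels)
  if (n == 0L) return(pixels)
  r0 <- min(pixels[, 1L]); c0 <- min(pixels[, 2L])
  h <- max(pixels[, 1L]) - r0 + 1L; w <- max(pixels[, 2L]) - c0 + 1L
  m <- matrix(FALSE, h + 2L, w + 2L)
  lr <- pixels[, 1L] - r0 + 2L; lc <- pixels[, 2L] - c0 + 2L
  m[cbind(lr, lc)] <- TRUE
  nb <- matrix(0L, h + 2L, w + 2L)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    nb[2:(h + 1L), 2:(w + 1L)] <- nb[2:(h + 1L), 2:(w + 1L)] +
      m[2:(h + 1L) + dr, 2:(w + 1L) + dc]
  }
  onb <- nb[cbind(lr, lc)]
  pixels[onb < 8L, , drop = FALSE]
}
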