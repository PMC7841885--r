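# Brute-force reference implementations, kept deliberately naive and
# independent of the package's vectorised code paths.

# edge-inclusive symmetric reflection of an out-of-range index
oracle_reflect <- function(i, n) {
  repeat {
    if (i < 1) i <- 1 - i
    else if (i > n) i <- 2 * n + 1 - i
    else return(i)
  }
}

# per-pixel window mean by direct summation
oracle_local_mean <- function(img, wsize) {
  r <- (wsize - 1) / 2
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    s <- 0
    for (di in -r:r) for (dj in -r:r)
      s <- s + img[oracle_reflect(i + di, nr), oracle_reflect(j + dj, nc)]
    out[i, j] <- s / wsize^2
  }
  out
}

oracle_adaptive_threshold <- function(img, wsize, C)
  img < oracle_local_mean(img, wsize) - C

# the eight canonical compass kernels, typed out literally
oracle_kirsch_masks <- list(
  rbind(c( 5,  5,  5), c(-3,  0, -3), c(-3, -3, -3)),
  rbind(c(-3,  5,  5), c(-3,  0,  5), c(-3, -3, -3)),
  rbind(c(-3, -3,  5), c(-3,  0,  5), c(-3, -3,  5)),
  rbind(c(-3, -3, -3), c(-3,  0,  5), c(-3,  5,  5)),
  rbind(c(-3, -3, -3), c(-3,  0, -3), c( 5,  5,  5)),
  rbind(c(-3, -3, -3), c( 5,  0, -3), c( 5,  5, -3)),
  rbind(c( 5, -3, -3), c( 5,  0, -3), c( 5, -3, -3)),
  rbind(c( 5,  5, -3), c( 5,  0, -3), c(-3, -3, -3))
)

oracle_kirsch_response <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    best <- 0
    for (K in oracle_kirsch_masks) {
      s <- 0
      for (a in 1:3) for (b in 1:3)
        s <- s + K[a, b] *
          img[oracle_reflect(i + a - 2, nr), oracle_reflect(j + b - 2, nc)]
      if (s > best) best <- s
    }
    out[i, j] <- best
  }
  out
}

# hull-pixel membership by the angular-gap criterion: a point is outside
# the convex hull of S iff the directions towards the points of S leave
# an angular gap wider than pi.
oracle_in_hull <- function(qr, qc, pixels) {
  dr <- pixels[, 1] - qr; dc <- pixels[, 2] - qc
  zero <- dr == 0 & dc == 0
  if (any(zero)) return(TRUE)
  ang <- sort(atan2(dr, dc))
  gaps <- c(diff(ang), 2 * pi - (ang[length(ang)] - ang[1]))
  max(gaps) <= pi + 1e-9
}

oracle_solidity <- function(pixels) {
  n <- nrow(pixels)
  if (n <= 2) return(1)
  # collinear check
  dr <- pixels[, 1] - pixels[1, 1]; dc <- pixels[, 2] - pixels[1, 2]
  k <- which(dr != 0 | dc != 0)[1]
  cross <- dr * dc[k] - dc * dr[k]
  if (all(abs(cross) < 1e-9)) return(1)
  cnt <- 0
  for (r in min(pixels[, 1]):max(pixels[, 1]))
    for (c in min(pixels[, 2]):max(pixels[, 2]))
      if (oracle_in_hull(r, c, pixels)) cnt <- cnt + 1
  n / cnt
}

oracle_inertia_ratio <- function(pixels) {
  if (nrow(pixels) < 2) return(1)
  M <- stats::cov.wt(pixels, method = "ML")$cov
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  if (ev[1] < 1e-12) return(1)
  sqrt(max(ev[2], 0) / ev[1])
}

oracle_dice <- function(idxA, idxB)
  2 * length(intersect(idxA, idxB)) / (length(idxA) + length(idxB))

# naive AJI: per ground-truth instance in ascending label order, pick the
# unused prediction with the highest Jaccard (ties: lowest label)
oracle_aji <- function(gt, pred) {
  gl <- sort(setdiff(unique(as.vector(gt)), 0))
  pl <- sort(setdiff(unique(as.vector(pred)), 0))
  used <- rep(FALSE, length(pl))
  num <- 0; den <- 0
  for (g in gl) {
    G <- which(gt == g)
    bestJ <- -1; bestP <- 0
    for (k in seq_along(pl)) {
      if (used[k]) next
      P <- which(pred == pl[k])
      inter <- length(intersect(G, P))
      if (inter == 0) next
      j <- inter / length(union(G, P))
      if (j > bestJ) { bestJ <- j; bestP <- k }
    }
    if (bestP > 0) {
      P <- which(pred == pl[bestP])
      num <- num + length(intersect(G, P))
      den <- den + length(union(G, P))
      used[bestP] <- TRUE
    } else den <- den + length(G)
  }
  for (k in seq_along(pl))
    if (!used[k]) den <- den + sum(pred == pl[k])
  num / den
}
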