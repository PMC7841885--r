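# Reflect-padded grid convolution primitives shared by the smoothing,
# thresholding and compass-gradient stages. Reflection is edge-inclusive
# (symmetric): ... 2 1 | 1 2 3 ... n | n n-1 ..., tiled as needed so the
# padding radius may exceed the image size.

.reflectIndex <- function(i, n) {
  j <- (i - 1L) %% (2L * n)
  ifelse(j < n, j + 1L, 2L * n - j)
}

.padReflect <- function(m, r) {
  if (r == 0L) return(m)
  ri <- .reflectIndex((1L - r):(nrow(m) + r), nrow(m))
  ci <- .reflectIndex((1L - r):(ncol(m) + r), ncol(m))
  m[ri, ci, drop = FALSE]
}

# Separable correlation with a 1-D kernel applied along both axes.
.sepConvolve <- function(img, k) {
  r <- (length(k) - 1L) %/% 2L
  if (r == 0L) return(img * k)
  nr <- nrow(img); nc <- ncol(img)
  p <- .padReflect(img, r)
  tmp <- matrix(0, nrow(p), nc)
  for (t in 0:(2L * r))
    tmp <- tmp + k[t + 1L] * p[, (1L + t):(nc + t), drop = FALSE]
  out <- matrix(0, nr, nc)
  for (t in 0:(2L * r))
    out <- out + k[t + 1L] * tmp[(1L + t):(nr + t), , drop = FALSE]
  out
}

# Correlation of a reflect-padded image with one 3x3 kernel.
.correlate3x3 <- function(p, K, nr, nc) {
  out <- matrix(0, nr, nc)
  for (a in 1:3)
    for (b in 1:3)
      if (K[a, b] != 0)
        out <- out + K[a, b] *
          p[a:(nr + a - 1L), b:(nc + b - 1L), drop = FALSE]
  out
}

# Mean over the wsize x wsize window centred on each pixel, computed
# exactly with an integral image over the reflect-padded grid.
.localBoxMean <- function(img, wsize) {
  r <- (wsize - 1L) %/% 2L
  nr <- nrow(img); nc <- ncol(img)
  p <- .padReflect(img, r)
  S <- cbind(0, rbind(0, apply(p, 2L, cumsum)))
  S <- t(apply(S, 1L, cumsum))
  hi_r <- (2L * r + 1L) + (1:nr); lo_r <- 1:nr
  hi_c <- (2L * r + 1L) + (1:nc); lo_c <- 1:nc
  (S[hi_r, hi_c] - S[lo_r, hi_c] - S[hi_r, lo_c] + S[lo_r, lo_c]) / wsize^2
}

# 1-D Gaussian tap vector for an odd kernel size; sigma follows the usual
# size-derived rule sigma = 0.3 * ((k - 1)/2 - 1) + 0.8.
.gaussianKernel1d <- function(ksize) {
  if (ksize == 1L) return(1)
  r <- (ksize - 1L) %/% 2L
  sigma <- 0.3 * ((ksize - 1) * 0.5 - 1) + 0.8
  x <- (-r):r
  k <- exp(-(x^2) / (2 * sigma^2))
  k / sum(k)
}
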