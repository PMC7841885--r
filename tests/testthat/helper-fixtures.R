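# Small geometric fixture builders used across the test files.

# pixels of a filled axis-aligned ellipse as an n x 2 (row, col) matrix
disc_pixels <- function(cr, cc, a, b = a) {
  g <- expand.grid(row = floor(cr - a):ceiling(cr + a),
                   col = floor(cc - b):ceiling(cc + b))
  keep <- ((g$row - cr) / a)^2 + ((g$col - cc) / b)^2 <= 1
  cbind(row = g$row[keep], col = g$col[keep])
}

# logical mask with the given pixel set on an nr x nc canvas
pixels_to_mask <- function(pixels, nr, nc) {
  m <- matrix(FALSE, nr, nc)
  m[pixels] <- TRUE
  m
}

region_of <- function(pixels, label = 1L) {
  o <- order(pixels[, 1], pixels[, 2])
  list(label = label, pixels = pixels[o, , drop = FALSE])
}

# random connected-ish pixel cloud (unique points in a small window)
random_pixels <- function(nmax = 60, span = 15) {
  n <- sample(3:nmax, 1)
  px <- unique(cbind(row = sample.int(span, n, replace = TRUE),
                     col = sample.int(span, n, replace = TRUE)))
  px
}

# random instance label mask made of non-overlapping rectangles
random_label_mask <- function(nr = 32, nc = 32, kmax = 4) {
  lab <- matrix(0L, nr, nc)
  k <- sample.int(kmax, 1)
  for (i in seq_len(k)) {
    h <- sample(2:6, 1); w <- sample(2:6, 1)
    r <- sample.int(nr - h, 1); c <- sample.int(nc - w, 1)
    if (all(lab[r:(r + h), c:(c + w)] == 0L))
      lab[r:(r + h), c:(c + w)] <- i
  }
  nucseg:::.relabel(lab)
}

# an easy bright-field scene: dark discs (the gt) on a bright background
disc_scene <- function(centers, radii, nr = 96, nc = 96,
                       intensity = 60, background = 220) {
  img <- matrix(background, nr, nc)
  gt <- matrix(0L, nr, nc)
  for (i in seq_along(radii)) {
    px <- disc_pixels(centers[[i]][1], centers[[i]][2], radii[i])
    img[px] <- intensity
    gt[px] <- i
  }
  list(image = img, gt = gt)
}
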