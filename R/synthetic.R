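# Seeded generator of cytology-like fixtures: dark elliptical nuclei
# centred in brighter cytoplasm ellipses on a bright background, plus
# elongated/concave artifacts and sub-threshold speckles that exercise
# the shape filters, with a ground-truth instance mask of the nuclei.

#' Specification for a synthetic cytology fixture
#'
#' Intensity layout follows the qualitative appearance of Pap smear
#' material: the nucleus is the darkest region within its cytoplasm, the
#' background the brightest. Defaults: nuclei 40-80, cytoplasm 140-180,
#' background 230, noise sd 5, 4-8 nuclei of semi-axes 6-14 px on a
#' 256x256 canvas, with 2 artifacts (alternating thin bars and concave
#' crescents) and 8 dark speckles.
#'
#' @param imageSize `(height, width)` in pixels.
#' @param nNuclei a single count or a `(min, max)` range.
#' @param nucleusAxes `(min, max)` semi-axis range in pixels.
#' @param nucleusIntensity,cytoplasmIntensity `(min, max)` intensity
#'   ranges; each nucleus/cytoplasm is uniform at a sampled level.
#' @param backgroundIntensity background level.
#' @param noiseSd additive Gaussian noise standard deviation (levels).
#' @param nArtifacts count of non-nucleus distractors (odd indices are
#'   thin bars with inertia ratio < 0.2, even indices concave crescents
#'   with solidity < 0.6).
#' @param nSpeckles count of 1-pixel dark dots (below any sensible
#'   MinSize).
#' @param seed integer seed; identical seeds give bit-identical output.
#' @param rgb return a 3-channel array with the signal in the green
#'   channel (red/blue are uninformative constants), emulating stained
#'   RGB scans.
#' @return a validated spec list for [generateCytology()].
#' @export
syntheticSpec <- function(imageSize = c(256, 256), nNuclei = c(4, 8),
                          nucleusAxes = c(6, 14),
                          nucleusIntensity = c(40, 80),
                          cytoplasmIntensity = c(140, 180),
                          backgroundIntensity = 230, noiseSd = 5,
                          nArtifacts = 2, nSpeckles = 8, seed = 1,
                          rgb = FALSE) {
  spec <- list(imageSize = imageSize, nNuclei = nNuclei,
               nucleusAxes = nucleusAxes,
               nucleusIntensity = nucleusIntensity,
               cytoplasmIntensity = cytoplasmIntensity,
               backgroundIntensity = backgroundIntensity,
               noiseSd = noiseSd, nArtifacts = nArtifacts,
               nSpeckles = nSpeckles, seed = seed, rgb = rgb)
  if (max(nucleusIntensity) >= min(cytoplasmIntensity) ||
      max(cytoplasmIntensity) >= backgroundIntensity)
    stop("need nucleus < cytoplasm < background intensities",
         call. = FALSE)
  if (length(imageSize) != 2L || any(imageSize < 32))
    stop("'imageSize' must be (height, width), each >= 32", call. = FALSE)
  if (noiseSd < 0 || nArtifacts < 0 || nSpeckles < 0)
    stop("counts and noise sd must be non-negative", call. = FALSE)
  spec
}

# pixels of a rotated filled ellipse, clipped to the canvas
.ellipsePixels <- function(cr, cc, a, b, theta, nr, nc) {
  R <- ceiling(max(a, b)) + 1L
  rows <- max(1L, floor(cr - R)):min(nr, ceiling(cr + R))
  cols <- max(1L, floor(cc - R)):min(nc, ceiling(cc + R))
  g <- expand.grid(row = rows, col = cols)
  dy <- g$row - cr; dx <- g$col - cc
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  keep <- (u / a)^2 + (v / b)^2 <= 1
  cbind(row = g$row[keep], col = g$col[keep])
}

# pixels of a rotated filled bar (rectangle) of half-length hl, half-width hw
.barPixels <- function(cr, cc, hl, hw, theta, nr, nc) {
  R <- ceiling(hl) + 1L
  rows <- max(1L, floor(cr - R)):min(nr, ceiling(cr + R))
  cols <- max(1L, floor(cc - R)):min(nc, ceiling(cc + R))
  g <- expand.grid(row = rows, col = cols)
  dy <- g$row - cr; dx <- g$col - cc
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  keep <- abs(u) <= hl & abs(v) <= hw
  cbind(row = g$row[keep], col = g$col[keep])
}

.runif1 <- function(range) {
  if (length(range) == 1L) range else runif(1L, range[1L], range[2L])
}

#' Generate one synthetic cytology image with ground truth
#'
#' Draws the cytoplasm ellipses, then the nuclei (labelled `1..K` in
#' placement order in the ground-truth mask), then artifacts and
#' speckles (present in the image, absent from the ground truth), then
#' adds rounded, clamped Gaussian noise. Nuclei are placed fully inside
#' the canvas, mutually non-overlapping with a 2-pixel margin; placement
#' failing after 200 retries raises an error.
#'
#' @param spec a spec from [syntheticSpec()].
#' @return a list with `image` (intensity matrix, or a 3-channel array
#'   when `spec$rgb`), `gt` (integer label mask) and `manifest` (a
#'   `data.frame` of per-nucleus centre, semi-axes, angle, intensity and
#'   axis ratio).
#' @examples
#' fx <- generateCytology(syntheticSpec(seed = 7))
#' max(fx$gt)           # number of nuclei
#' fx$manifest$axis_ratio
#' @export
generateCytology <- function(spec = syntheticSpec()) {
  oldSeed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(oldSeed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", oldSeed, envir = globalenv())
  })
  set.seed(spec$seed)

  nr <- spec$imageSize[1L]; nc <- spec$imageSize[2L]
  img <- matrix(spec$backgroundIntensity, nr, nc)
  gt <- matrix(0L, nr, nc)
  blocked <- matrix(FALSE, nr, nc)  # nuclei + margin: keep-out zone

  K <- if (length(spec$nNuclei) == 2L)
    sample(spec$nNuclei[1L]:spec$nNuclei[2L], 1L) else spec$nNuclei

  cells <- vector("list", K)
  k <- 0L
  while (k < K) {
    placed <- FALSE
    for (try in seq_len(200L)) {
      ax <- sort(runif(2L, spec$nucleusAxes[1L], spec$nucleusAxes[2L]))
      a <- ax[2L]; b <- max(ax[1L], 0.45 * a)
      theta <- runif(1L, 0, pi)
      margin <- ceiling(a) + 2L
      if (nr - margin < margin + 1L || nc - margin < margin + 1L)
        next
      cr <- runif(1L, margin + 1L, nr - margin)
      cc <- runif(1L, margin + 1L, nc - margin)
      guard <- .ellipsePixels(cr, cc, a + 2, b + 2, theta, nr, nc)
      if (any(blocked[guard])) next
      cells[[k + 1L]] <- list(
        cr = cr, cc = cc, a = a, b = b, theta = theta,
        nucInt = round(.runif1(spec$nucleusIntensity)),
        cytInt = round(.runif1(spec$cytoplasmIntensity)),
        cytScale = runif(1L, 2.2, 3))
      blocked[guard] <- TRUE
      placed <- TRUE
      break
    }
    if (!placed)
      stop("could not place nucleus ", k + 1L, " after 200 retries",
           call. = FALSE)
    k <- k + 1L
  }

  for (cell in cells) {
    cyt <- .ellipsePixels(cell$cr, cell$cc, cell$a * cell$cytScale,
                          cell$b * cell$cytScale, cell$theta, nr, nc)
    img[cyt] <- cell$cytInt
  }
  manifest <- vector("list", K)
  for (i in seq_len(K)) {
    cell <- cells[[i]]
    nuc <- .ellipsePixels(cell$cr, cell$cc, cell$a, cell$b, cell$theta,
                          nr, nc)
    img[nuc] <- cell$nucInt
    gt[nuc] <- i
    manifest[[i]] <- data.frame(
      label = i, center_row = cell$cr, center_col = cell$cc,
      major = cell$a, minor = cell$b, angle = cell$theta,
      intensity = cell$nucInt, axis_ratio = cell$b / cell$a,
      area = nrow(nuc))
  }

  darkInt <- function() round(.runif1(spec$nucleusIntensity))
  placeArtifact <- function(drawFn) {
    for (try in seq_len(200L)) {
      px <- drawFn()
      if (nrow(px) && !any(blocked[px])) {
        img[px] <<- darkInt()
        return(invisible())
      }
    }
    stop("could not place artifact after 200 retries", call. = FALSE)
  }
  for (j in seq_len(spec$nArtifacts)) {
    if (j %% 2L == 1L) {
      placeArtifact(function() .barPixels(
        runif(1L, 10, nr - 10), runif(1L, 10, nc - 10),
        hl = runif(1L, 15, 30), hw = runif(1L, 0.8, 1.6),
        theta = runif(1L, 0, pi), nr, nc))
    } else {
      placeArtifact(function() {
        cr <- runif(1L, 15, nr - 15); cc <- runif(1L, 15, nc - 15)
        theta <- runif(1L, 0, pi)
        a <- runif(1L, 9, 12); b <- runif(1L, 6, 9)
        e1 <- .ellipsePixels(cr, cc, a, b, theta, nr, nc)
        shift <- 0.55 * a
        e2 <- .ellipsePixels(cr + shift * sin(theta),
                             cc + shift * cos(theta),
                             a, b, theta, nr, nc)
        key1 <- (e1[, 2L] - 1L) * nr + e1[, 1L]
        key2 <- (e2[, 2L] - 1L) * nr + e2[, 1L]
        e1[!(key1 %in% key2), , drop = FALSE]
      })
    }
  }

  if (spec$nSpeckles > 0) {
    placedSpeckles <- 0L
    while (placedSpeckles < spec$nSpeckles) {
      pr <- sample.int(nr, 1L); pc <- sample.int(nc, 1L)
      if (blocked[pr, pc]) next
      img[pr, pc] <- darkInt()
      placedSpeckles <- placedSpeckles + 1L
    }
  }

  if (spec$noiseSd > 0)
    img <- img + rnorm(nr * nc, 0, spec$noiseSd)
  img <- round(pmin(pmax(img, 0), 255))

  if (isTRUE(spec$rgb)) {
    out <- array(0, dim = c(nr, nc, 3L))
    out[, , 1L] <- 205
    out[, , 2L] <- img
    out[, , 3L] <- 150
    img <- out
  }
  list(image = img, gt = gt,
       manifest = do.call(rbind, manifest))
}
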