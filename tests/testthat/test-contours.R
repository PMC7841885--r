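test_that("region extraction finds 8-connected components in raster order", {
  expect_identical(extractRegions(matrix(FALSE, 5, 5)), list())

  m <- matrix(FALSE, 9, 9); m[2:4, 2:4] <- TRUE; m[6:8, 6:8] <- TRUE
  regs <- extractRegions(m)
  expect_length(regs, 2)
  expect_equal(vapply(regs, function(r) nrow(r$pixels), 0L), c(9L, 9L))
  expect_equal(vapply(regs, `[[`, 0L, "label"), 1:2)

  # diagonal contact joins components
  d <- matrix(FALSE, 4, 4); d[2, 2] <- TRUE; d[3, 3] <- TRUE
  expect_length(extractRegions(d), 1)

  # labels follow raster order of the first-encountered pixel
  m2 <- matrix(FALSE, 6, 10)
  m2[4, 2] <- TRUE          # first encountered at row 4
  m2[2, 8] <- TRUE          # first encountered at row 2 -> label 1
  regs2 <- extractRegions(m2)
  expect_equal(regs2[[1]]$pixels[1, ], c(row = 2, col = 8))
  expect_equal(regs2[[2]]$pixels[1, ], c(row = 4, col = 2))
})

test_that("holes are filled before feature computation", {
  ring <- matrix(FALSE, 9, 9)
  ring[3:7, 3:7] <- TRUE; ring[4:6, 4:6] <- FALSE
  regs <- extractRegions(ring)
  expect_length(regs, 1)
  expect_equal(nrow(regs[[1]]$pixels), 25)  # filled 5x5 block
  # background touching the border is not a hole
  open <- matrix(FALSE, 5, 9); open[1:4, 3:7] <- TRUE; open[1:3, 4:6] <- FALSE
  expect_equal(nrow(extractRegions(open)[[1]]$pixels), sum(open))
})

test_that("solidity is 1 for convex shapes and matches the exhaustive oracle", {
  rect <- as.matrix(expand.grid(row = 2:5, col = 3:8))
  expect_equal(regionSolidity(rect), 1)
  expect_equal(regionSolidity(cbind(row = 4, col = 7)), 1)    # single pixel
  expect_equal(regionSolidity(cbind(row = 1:5, col = rep(2, 5))), 1)  # line

  # plus-shaped region: concavities at the four corners
  plus <- matrix(FALSE, 5, 5); plus[2:4, ] <- TRUE; plus[, 2:4] <- TRUE
  px <- which(plus, arr.ind = TRUE); colnames(px) <- c("row", "col")
  expect_equal(regionSolidity(px), oracle_solidity(px))

  set.seed(11)
  for (i in 1:30) {
    px <- random_pixels()
    expect_equal(regionSolidity(px), oracle_solidity(px), tolerance = 1e-9)
  }
  expect_error(regionSolidity(px[0, , drop = FALSE]), "empty")
})

test_that("inertia ratio is the equivalent-ellipse axis ratio", {
  expect_equal(regionInertiaRatio(disc_pixels(30, 30, 15)), 1,
               tolerance = 0.05)
  expect_lt(regionInertiaRatio(cbind(row = rep(5, 50), col = 1:50)), 0.1)
  expect_equal(regionInertiaRatio(disc_pixels(40, 40, 20, 10)), 0.5,
               tolerance = 0.05)
  expect_equal(regionInertiaRatio(cbind(row = 3, col = 4)), 1)  # degenerate

  set.seed(12)
  for (i in 1:30) {
    px <- random_pixels(nmax = 200, span = 40)
    expect_equal(regionInertiaRatio(px), oracle_inertia_ratio(px),
                 tolerance = 1e-9)
  }
})

test_that("the contour filter applies exactly the stated predicate", {
  img <- matrix(128, 40, 160)

  p <- nucleusParams(minSolidity = 0.8, minSize = 5, maxSize = 70,
                     minInertia = 0.2)

  # low solidity is rejected: a thin L-shaped region
  ell <- rbind(as.matrix(expand.grid(row = 1:24, col = 1:4)),
               as.matrix(expand.grid(row = 21:24, col = 5:24)))
  colnames(ell) <- c("row", "col")
  lowSol <- region_of(ell)
  expect_lt(regionSolidity(ell), 0.8)
  expect_length(filterRegions(list(lowSol), img, p), 0)

  expect_identical(filterRegions(list(), img, p), list())

  # boundary-size window: sizes 4, 30, 500 with [5, 70] keeps only 30
  tiny <- region_of(as.matrix(expand.grid(row = 1:2, col = 1:2)))
  mid <- region_of(as.matrix(expand.grid(row = 1:8, col = 1:9)))
  big <- region_of(as.matrix(expand.grid(row = 1:126, col = 1:126)))
  ftall <- regionFeatures(list(tiny, mid, big), matrix(128, 130, 130))
  expect_equal(ftall$size, c(4, 30, 500))
  kept <- filterRegions(list(tiny, mid, big), matrix(128, 130, 130), p)
  expect_length(kept, 1)
  expect_equal(nrow(kept[[1]]$pixels), 72)

  # every survivor satisfies the predicate verbatim
  set.seed(13)
  regs <- lapply(1:20, function(i) region_of(random_pixels(nmax = 80)))
  pr <- nucleusParams(minSolidity = 0.5, minSize = 3, maxSize = 40,
                      minInertia = 0.2)
  out <- filterRegions(regs, matrix(100, 15, 15), pr)
  for (r in out) {
    ft <- regionFeatures(r, matrix(100, 15, 15))
    expect_true(ft$size >= 3 && ft$size <= 40 &&
                ft$solidity >= 0.5 && ft$inertia_ratio >= 0.2)
  }
  # order preserved
  labs <- vapply(out, `[[`, 0L, "label")
  expect_identical(labs, sort(labs))
})

test_that("filter acceptance is anti-monotone in its thresholds", {
  set.seed(14)
  img <- matrix(100, 15, 15)
  regs <- lapply(1:15, function(i) region_of(random_pixels(nmax = 80), i))
  base <- nucleusParams(minSolidity = 0.5, minSize = 3, maxSize = 40,
                        minInertia = 0.2)
  n0 <- length(filterRegions(regs, img, base))
  tighter <- list(
    updateParams(base, MinSolid = 0.7),
    updateParams(base, MinInertia = 0.4),
    updateParams(base, MinSize = 6),
    updateParams(base, MaxSize = 25)
  )
  for (p in tighter)
    expect_lte(length(filterRegions(regs, img, p)), n0)
})
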