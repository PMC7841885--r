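p_grow <- nucleusParams(Irange = 10, minSize = 2, maxSize = 100,
                        minSolidity = 0.5, minInertia = 0)

test_that("growth stops immediately when no neighbour is within Irange", {
  img <- matrix(200, 11, 11)
  img[4:8, 4:8] <- 50
  seed <- region_of(as.matrix(expand.grid(row = 4:8, col = 4:8)))
  out <- growRegion(seed, img, p_grow)
  expect_identical(out$pixels, seed$pixels)
})

test_that("a region already beyond MaxSize is returned unchanged", {
  img <- matrix(50, 40, 40)  # everything admissible
  big <- region_of(as.matrix(expand.grid(row = 2:32, col = 2:32)))
  pSmall <- updateParams(p_grow, MaxSize = 30)  # boundary is 120 > 30
  out <- growRegion(big, img, pSmall)
  expect_identical(out$pixels, big$pixels)
})

test_that("an eroded uniform square grows back to the full square", {
  img <- matrix(220, 15, 15)
  img[4:12, 4:12] <- 60                     # 9x9 dark square
  seed <- region_of(as.matrix(expand.grid(row = 6:10, col = 6:10)))
  out <- growRegion(seed, img, p_grow)
  full <- as.matrix(expand.grid(row = 4:12, col = 4:12))
  full <- full[order(full[, 1], full[, 2]), ]
  expect_equal(unname(out$pixels), unname(full))

  # brute-force BFS with the same admission rule reaches the same set
  bfs <- which(img == 60)
  expect_setequal((out$pixels[, 2] - 1) * 15 + out$pixels[, 1], bfs)
})

test_that("Irange = 0 on a contrasting boundary is a fixed point", {
  img <- matrix(199, 9, 9)
  img[4:6, 4:6] <- 60
  seed <- region_of(as.matrix(expand.grid(row = 4:6, col = 4:6)))
  out <- growRegion(seed, img, updateParams(p_grow, Irange = 0))
  expect_identical(out$pixels, seed$pixels)
})

test_that("growth is monotone (superset) and deterministic", {
  set.seed(21)
  for (i in 1:8) {
    fx <- generateCytology(syntheticSpec(imageSize = c(64, 64),
                                         nNuclei = 1, nArtifacts = 0,
                                         nSpeckles = 0, seed = 300 + i))
    px <- which(fx$gt == 1, arr.ind = TRUE)
    colnames(px) <- c("row", "col")
    # erode the seed: drop boundary pixels
    bd <- nucseg:::.regionBoundary(px)
    keep <- !(paste(px[, 1], px[, 2]) %in% paste(bd[, 1], bd[, 2]))
    seed <- region_of(px[keep, , drop = FALSE])
    out1 <- growRegion(seed, fx$image, p_grow)
    out2 <- growRegion(seed, fx$image, p_grow)
    expect_identical(out1, out2)
    expect_true(all(paste(seed$pixels[, 1], seed$pixels[, 2]) %in%
                    paste(out1$pixels[, 1], out1$pixels[, 2])))
  }
})

test_that("recoverAll keeps regions disjoint and is label-deterministic", {
  expect_identical(recoverAll(list(), matrix(100, 8, 8), p_grow),
                   matrix(0L, 8, 8))

  # growth blocked everywhere: mask has exactly the seed pixels
  img <- matrix(200, 11, 11); img[4:8, 4:8] <- 50
  seed <- region_of(as.matrix(expand.grid(row = 4:8, col = 4:8)))
  mask <- recoverAll(list(seed), img, p_grow)
  expect_equal(sum(mask == 1L), 25)
  expect_equal(sum(mask), 25)

  # two seeds inside one uniform blob partition it without overlap
  img2 <- matrix(230, 13, 21)
  img2[3:11, 3:19] <- 60
  s1 <- region_of(as.matrix(expand.grid(row = 6:8, col = 5:7)), 1L)
  s2 <- region_of(as.matrix(expand.grid(row = 6:8, col = 14:16)), 2L)
  pBig <- updateParams(p_grow, MaxSize = 1000, Irange = 5)
  m2 <- recoverAll(list(s1, s2), img2, pBig)
  areas <- tabulate(m2[m2 > 0])
  expect_equal(sum(areas), sum(m2 > 0))        # disjoint labels
  expect_equal(length(areas), 2)
  expect_true(all(areas >= 9))
  # deterministic
  expect_identical(m2, recoverAll(list(s1, s2), img2, pBig))

  # overlapping input regions are refused
  s3 <- region_of(as.matrix(expand.grid(row = 6:8, col = 6:8)), 2L)
  expect_error(recoverAll(list(s1, s3), img2, pBig), "overlap")
})
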