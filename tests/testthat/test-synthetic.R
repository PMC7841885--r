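test_that("generation is a pure function of the seed", {
  a <- generateCytology(syntheticSpec(seed = 5))
  b <- generateCytology(syntheticSpec(seed = 5))
  expect_identical(a, b)
  c <- generateCytology(syntheticSpec(seed = 6))
  expect_false(identical(a$image, c$image))
  # the caller's RNG stream is left untouched
  set.seed(99); before <- runif(3)
  set.seed(99); invisible(generateCytology(syntheticSpec(seed = 5)))
  expect_identical(runif(3), before)
})

test_that("nucleus count, labels and manifest geometry are consistent", {
  fx <- generateCytology(syntheticSpec(nNuclei = 5, noiseSd = 0,
                                       nArtifacts = 0, nSpeckles = 0,
                                       seed = 17))
  expect_equal(max(fx$gt), 5)
  expect_equal(sort(unique(as.vector(fx$gt))), 0:5)
  expect_equal(nrow(fx$manifest), 5)
  for (i in 1:5) {
    px <- which(fx$gt == i, arr.ind = TRUE)
    expect_equal(regionInertiaRatio(px), fx$manifest$axis_ratio[i],
                 tolerance = 0.05)
    expect_equal(nrow(px), fx$manifest$area[i])
    # nuclei are uniform at their manifest intensity (no noise)
    expect_true(all(fx$image[px] == fx$manifest$intensity[i]))
  }
  zero <- generateCytology(syntheticSpec(nNuclei = 0, seed = 1))
  expect_equal(max(zero$gt), 0)
})

test_that("intensity layering and rgb encoding hold", {
  fx <- generateCytology(syntheticSpec(noiseSd = 0, seed = 23))
  nuc <- fx$image[fx$gt > 0]
  rest <- fx$image[fx$gt == 0]
  expect_lt(max(nuc), 140)                    # nuclei darkest
  expect_equal(max(fx$image), 230)            # background brightest

  rgbFx <- generateCytology(syntheticSpec(noiseSd = 0, seed = 23,
                                          rgb = TRUE))
  expect_equal(dim(rgbFx$image)[3], 3)
  expect_equal(toGrayscale(rgbFx$image), fx$image)

  expect_error(syntheticSpec(nucleusIntensity = c(40, 200)), "intensities")
})

test_that("artifacts and speckles are present in the image but not the gt", {
  spec <- syntheticSpec(nNuclei = 3, nArtifacts = 2, nSpeckles = 6,
                        noiseSd = 0, seed = 29)
  fx <- generateCytology(spec)
  expect_equal(max(fx$gt), 3)
  # dark pixels outside the gt exist (artifacts/speckles)
  darkOutside <- fx$image <= max(spec$nucleusIntensity) & fx$gt == 0
  expect_gt(sum(darkOutside), 20)
  # distractors have non-nucleus shape: at least one elongated (bar) and
  # one concave (crescent) component among the dark outside regions
  regs <- extractRegions(pixels_to_mask(which(darkOutside, arr.ind = TRUE),
                                        nrow(fx$image), ncol(fx$image)),
                         fill = FALSE)
  regs <- regs[vapply(regs, function(r) nrow(r$pixels), 0L) > 10]
  inertia <- vapply(regs, function(r) regionInertiaRatio(r$pixels), 0)
  solidity <- vapply(regs, function(r) regionSolidity(r$pixels), 0)
  expect_true(any(inertia < 0.2))
  expect_true(any(solidity < 0.6))
})

test_that("every gt nucleus passes the filter under its drawn geometry", {
  fx <- generateCytology(syntheticSpec(nNuclei = 6, noiseSd = 0,
                                       nArtifacts = 0, nSpeckles = 0,
                                       seed = 37))
  p <- nucleusParams(minSolidity = 0.9,
                     minSize = 4,
                     maxSize = ceiling(2 * pi * max(fx$manifest$major)) + 8,
                     minInertia = min(fx$manifest$axis_ratio) - 0.05)
  regs <- extractRegions(fx$gt > 0)
  expect_length(regs, 6)
  kept <- filterRegions(regs, fx$image, p)
  expect_length(kept, 6)
})
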