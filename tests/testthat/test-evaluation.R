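test_that("Dice coefficient follows the overlap formula", {
  a <- matrix(FALSE, 6, 6); a[1:2, 1:2] <- TRUE
  expect_equal(diceCoefficient(a, a), 1)
  b <- matrix(FALSE, 6, 6); b[5:6, 5:6] <- TRUE
  expect_equal(diceCoefficient(a, b), 0)
  c <- matrix(FALSE, 6, 6); c[2:3, 1:2] <- TRUE
  expect_equal(diceCoefficient(a, c), 0.5)   # |A|=|B|=4, overlap 2
  expect_equal(diceCoefficient(a, c), diceCoefficient(c, a))
  none <- matrix(FALSE, 6, 6)
  expect_error(diceCoefficient(none, none), "empty")
})

test_that("instance matching applies the 0.6 Dice gate", {
  gt <- matrix(0L, 20, 20)
  gt[2:5, 2:5] <- 1L; gt[10:14, 10:14] <- 2L; gt[17:19, 2:4] <- 3L
  m <- matchInstances(gt, gt)
  expect_equal(c(m$TP, m$FP, m$FN), c(3L, 0L, 0L))
  expect_equal(m$perNucleusDice, c(1, 1, 1))

  # overlap engineered to Dice exactly 0.59: below the gate
  gt1 <- matrix(0L, 20, 20); gt1[1:10, 1:10] <- 1L          # 100 px
  pr1 <- matrix(0L, 20, 20)
  pr1[which(gt1 == 1L)[1:59]] <- 1L                          # 59 shared
  pr1[which(gt1 == 0L)[1:41]] <- 1L                          # 41 outside
  expect_equal(diceCoefficient(gt1 == 1, pr1 == 1), 0.59)
  m1 <- matchInstances(gt1, pr1)
  expect_equal(c(m1$TP, m1$FP, m1$FN), c(0L, 1L, 1L))

  # one perfect match plus one spurious off-target blob
  gt2 <- matrix(0L, 20, 20); gt2[2:5, 2:5] <- 1L; gt2[10:13, 10:13] <- 2L
  pr2 <- matrix(0L, 20, 20); pr2[2:5, 2:5] <- 1L; pr2[16:19, 16:19] <- 2L
  m2 <- matchInstances(gt2, pr2)
  expect_equal(c(m2$TP, m2$FP, m2$FN), c(1L, 1L, 1L))

  expect_error(matchInstances(gt, matrix(0L, 5, 5)), "shape")
})

test_that("matching conserves instance counts on random mask pairs", {
  set.seed(31)
  for (i in 1:20) {
    gt <- random_label_mask()
    pred <- random_label_mask()
    m <- matchInstances(gt, pred)
    expect_identical(m$TP + m$FN, max(gt))
    expect_identical(m$TP + m$FP, max(pred))
  }
})

test_that("precision/recall/F1 reproduce the printed worked examples", {
  expect_equal(round(f1Score(0.978, 0.933), 3), 0.955)
  expect_equal(round(f1Score(0.938, 0.558), 3), 0.700)
  expect_equal(f1Score(1, 1), 1)
  expect_equal(f1Score(0, 0), 0)

  sc <- prfScores(TP = 8, FP = 2, FN = 2)
  expect_equal(unname(sc), c(0.8, 0.8, 0.8))
  expect_warning(prfScores(0, 0, 0), "undefined")

  # F1 lies between min and max of precision/recall
  set.seed(32)
  for (i in 1:25) {
    p <- runif(1); r <- runif(1)
    f <- f1Score(p, r)
    expect_gte(f, min(p, r) - 1e-12)
    expect_lte(f, max(p, r) + 1e-12)
  }
})

test_that("AJI accumulates matched unions plus unmatched predictions", {
  gt <- matrix(0L, 16, 16); gt[3:6, 3:6] <- 1L; gt[10:13, 9:12] <- 2L
  expect_equal(aggregatedJaccard(gt, gt), 1)
  expect_equal(aggregatedJaccard(gt, matrix(0L, 16, 16)), 0)

  # two 16-px squares overlapping by 8 px: 8 / 24
  g1 <- matrix(0L, 12, 12); g1[3:6, 3:6] <- 1L
  p1 <- matrix(0L, 12, 12); p1[3:6, 5:8] <- 1L
  expect_equal(aggregatedJaccard(g1, p1), 1 / 3)

  expect_error(aggregatedJaccard(matrix(0L, 4, 4), matrix(0L, 4, 4)),
               "undefined")
})

test_that("AJI matches the naive per-pair oracle on random masks", {
  set.seed(33)
  for (i in 1:25) {
    gt <- random_label_mask(kmax = 4)
    if (max(gt) == 0) next
    pred <- random_label_mask(kmax = 4)
    expect_equal(aggregatedJaccard(gt, pred), oracle_aji(gt, pred),
                 tolerance = 1e-12)
  }
})

test_that("batch evaluation pools counts and AJI parts across images", {
  gtA <- matrix(0L, 16, 16); gtA[2:5, 2:5] <- 1L
  gtB <- matrix(0L, 16, 16); gtB[4:9, 4:9] <- 1L; gtB[12:15, 12:15] <- 2L
  prA <- gtA
  prB <- matrix(0L, 16, 16); prB[4:9, 4:9] <- 1L   # misses instance 2
  ev <- evaluateBatch(list(gtA, gtB), list(prA, prB))
  expect_equal(unname(matchCounts(ev$pooled)), c(2L, 0L, 1L))
  expect_equal(precision(ev$pooled), 1)
  expect_equal(recall(ev$pooled), 2 / 3)
  expect_equal(nrow(ev$perImage), 2)
  # pooled AJI = summed numerators / summed denominators
  nA <- nucseg:::.ajiParts(gtA, prA); nB <- nucseg:::.ajiParts(gtB, prB)
  expect_equal(ajiScore(ev$pooled),
               unname((nA["num"] + nB["num"]) / (nA["den"] + nB["den"])))
  # evaluateMasks returns a well-formed S4 summary
  one <- evaluateMasks(gtB, prB)
  expect_s4_class(one, "NucleusEvaluation")
  expect_equal(unname(matchCounts(one)), c(1L, 0L, 1L))
  expect_equal(nucleusDice(one), 1)
})
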