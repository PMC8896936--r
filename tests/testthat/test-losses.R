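test_that("Dice loss matches hand-evaluated cases and limits", {
  # p = 0.5 on 8 voxels, 4 target voxels, smooth 1: 1 - (2*2+1)/(4+4+1) = 4/9
  p <- array(0.5, c(2, 2, 2))
  t <- array(c(1, 1, 1, 1, 0, 0, 0, 0), c(2, 2, 2))
  expect_equal(diceLoss(p, t, lossConfig(dice_smooth = 1)), 4 / 9,
               tolerance = 1e-12)
  # perfect prediction: -> 0 as smoothing -> 0
  pb <- array(c(1, 0, 1, 0, 0, 0, 1, 0), c(2, 2, 2))
  expect_lt(diceLoss(pb, pb, lossConfig(dice_smooth = 1e-6)), 1e-6)
  # no overlap: loss = 1 - s/(sum(t)+s)
  z <- array(0, c(2, 2, 2))
  expect_equal(diceLoss(z, t, lossConfig(dice_smooth = 1)), 1 - 1 / 5)
  expect_error(diceLoss(array(0.5, c(2, 2, 2)), array(0, c(2, 2, 3))),
               "mismatch")
})

test_that("Dice loss complements the Dice metric on binary predictions", {
  set.seed(8)
  for (i in 1:20) {
    pair <- randomMaskPair(c(8, 8, 8))
    dl <- diceLoss(voxelData(pair$a), voxelData(pair$b),
                   lossConfig(dice_smooth = 1e-6))
    dm <- diceMetric(pair$a, pair$b)
    expect_equal(dl, 1 - dm, tolerance = 1e-4)
  }
})

test_that("binary cross-entropy matches closed forms", {
  t <- array(c(1, 0, 0, 1, 1, 0, 0, 0), c(2, 2, 2))
  expect_lt(crossEntropyLoss(t, t), 1e-6)                # perfect, clamped
  expect_equal(crossEntropyLoss(array(0.5, c(2, 2, 2)), t), log(2),
               tolerance = 1e-9)
  expect_equal(crossEntropyLoss(array(0.25, c(1, 1, 1)), array(1, c(1, 1, 1))),
               -log(0.25), tolerance = 1e-9)
})

test_that("contour loss is zero for constants and matches a finite-difference oracle", {
  expect_identical(contourLoss(array(0.7, c(4, 4, 4))), 0)
  expect_identical(contourLoss(array(0, c(3, 5, 4))), 0)
  expect_error(contourLoss(array(0.5, c(1, 4, 4))), "2 voxels")
  # independent oracle: explicit central/one-sided differences by loops
  oracle <- function(p) {
    d <- dim(p)
    g2 <- array(0, d)
    for (z in 1:d[1]) for (y in 1:d[2]) for (x in 1:d[3]) {
      gz <- if (z == 1) p[2, y, x] - p[1, y, x]
            else if (z == d[1]) p[z, y, x] - p[z - 1, y, x]
            else (p[z + 1, y, x] - p[z - 1, y, x]) / 2
      gy <- if (y == 1) p[z, 2, x] - p[z, 1, x]
            else if (y == d[2]) p[z, y, x] - p[z, y - 1, x]
            else (p[z, y + 1, x] - p[z, y - 1, x]) / 2
      gx <- if (x == 1) p[z, y, 2] - p[z, y, 1]
            else if (x == d[3]) p[z, y, x] - p[z, y, x - 1]
            else (p[z, y, x + 1] - p[z, y, x - 1]) / 2
      g2[z, y, x] <- gz^2 + gy^2 + gx^2
    }
    mean(sqrt(g2))
  }
  step <- array(0, c(4, 4, 4)); step[, , 3:4] <- 1     # hard step along x
  expect_equal(contourLoss(step), oracle(step), tolerance = 1e-12)
  set.seed(9)
  r <- array(runif(5 * 4 * 6), c(5, 4, 6))
  expect_equal(contourLoss(r), oracle(r), tolerance = 1e-12)
  # positive homogeneity: halving p halves the loss
  expect_equal(contourLoss(0.5 * r), 0.5 * contourLoss(r), tolerance = 1e-12)
})

test_that("the composite loss is the sum of its parts", {
  set.seed(10)
  p <- array(runif(4^3), c(4, 4, 4))
  t <- array(rbinom(64, 1, 0.3), c(4, 4, 4))
  cfg <- lossConfig(contour_weight = 0.7)
  lv <- totalLoss(p, t, cfg)
  expect_equal(lv$total,
               diceLoss(p, t, cfg) + crossEntropyLoss(p, t) +
                 0.7 * contourLoss(p, cfg), tolerance = 1e-10)
  lv0 <- totalLoss(p, t, lossConfig(contour_weight = 0))
  expect_equal(lv0$total, lv0$l_dice + lv0$l_ce, tolerance = 1e-12)
  expect_true(all(unlist(lv) >= 0))
})

test_that("the analytic loss gradient matches finite differences", {
  set.seed(11)
  p <- array(runif(4^3, 0.05, 0.95), c(4, 4, 4))
  t <- array(rbinom(64, 1, 0.3), c(4, 4, 4))
  cfg <- lossConfig(contour_weight = 1)
  g <- totalLossGrad(p, t, cfg)
  idx <- sample(64, 10)
  for (ii in idx) {
    e <- 1e-6
    p1 <- p; p1[ii] <- p[ii] + e
    p2 <- p; p2[ii] <- p[ii] - e
    fd <- (totalLoss(p1, t, cfg)$total - totalLoss(p2, t, cfg)$total) / (2 * e)
    expect_equal(g[ii], fd, tolerance = 1e-3)
  }
})
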