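test_that("confusion counts agree with a per-voxel loop oracle", {
  set.seed(12)
  pair <- randomMaskPair(c(8, 8, 8))
  cm <- confusion(pair$a, pair$b)
  pa <- voxelData(pair$a); pb <- voxelData(pair$b)
  tp <- 0; fp <- 0; fn <- 0
  for (i in seq_along(pa)) {
    if (pa[i] == 1 && pb[i] == 1) tp <- tp + 1
    if (pa[i] == 1 && pb[i] == 0) fp <- fp + 1
    if (pa[i] == 0 && pb[i] == 1) fn <- fn + 1
  }
  expect_equal(cm, list(tp = tp, fp = fp, fn = fn))
  expect_equal(confusion(pair$a, pair$a)$fp, 0)
  expect_equal(confusion(pair$a, pair$a)$fn, 0)
  empty <- BinaryMask(array(0L, c(8, 8, 8)))
  cm2 <- confusion(empty, pair$b)
  expect_equal(cm2$tp, 0)
  expect_equal(cm2$fn, sum(pb))
})

test_that("Dice and IoU match hand values and their algebraic identity", {
  # tp=2, fp=1, fn=1 -> dice 4/6, iou 1/2
  p <- BinaryMask(array(c(1L, 1L, 1L, 0L, 0L, 0L, 0L, 0L), c(2, 2, 2)))
  t <- BinaryMask(array(c(1L, 1L, 0L, 1L, 0L, 0L, 0L, 0L), c(2, 2, 2)))
  expect_equal(diceMetric(p, t), 2 / 3, tolerance = 1e-12)
  expect_equal(iouMetric(p, t), 0.5, tolerance = 1e-12)
  expect_equal(diceMetric(p, p), 1)
  disj <- BinaryMask(array(c(0L, 0L, 0L, 0L, 1L, 1L, 0L, 0L), c(2, 2, 2)))
  expect_equal(diceMetric(p, disj), 0)
  set.seed(13)
  for (i in 1:100) {
    pair <- randomMaskPair(c(6, 6, 6))
    d <- diceMetric(pair$a, pair$b)
    j <- iouMetric(pair$a, pair$b)
    expect_equal(d, 2 * j / (1 + j), tolerance = 1e-12)
  }
})

test_that("surface voxels follow the 6-neighbour/border definition", {
  single <- array(0L, c(5, 5, 5)); single[3, 3, 3] <- 1L
  s1 <- surfaceVoxels(BinaryMask(single, spacing = c(2, 1, 1)))
  expect_equal(nrow(s1), 1L)
  expect_equal(unname(s1[1, ]), c(2 * 2, 2, 2))     # (index-1) * spacing, mm
  cube <- array(0L, c(7, 7, 7)); cube[3:5, 3:5, 3:5] <- 1L
  expect_equal(nrow(surfaceVoxels(BinaryMask(cube))), 26L)
  sheet <- array(0L, c(5, 5, 5)); sheet[3, , ] <- 1L
  expect_equal(nrow(surfaceVoxels(BinaryMask(sheet))), 25L)
  # a voxel on the volume border is surface even if fully surrounded inside
  solid <- array(1L, c(3, 3, 3))
  expect_equal(nrow(surfaceVoxels(BinaryMask(solid))), 26L)  # all but centre
  expect_warning(surfaceVoxels(BinaryMask(array(0L, c(3, 3, 3)))), "empty")
})

test_that("ASSD and Hausdorff match closed-form two-point cases", {
  a <- array(0L, c(5, 5, 5)); a[2, 2, 2] <- 1L
  b <- array(0L, c(5, 5, 5)); b[2, 2, 5] <- 1L
  ma <- BinaryMask(a); mb <- BinaryMask(b)
  expect_equal(assd(ma, mb), 3)                      # (3+3)/2
  h <- hausdorff(ma, mb)
  expect_equal(h$hd, 3)
  b4 <- array(0L, c(5, 5, 5)); b4[2, 2, 2] <- 1L
  a4 <- array(0L, c(5, 5, 5)); a4[2, 2, 2] <- 1L
  # two voxels 4 mm apart via spacing
  mb4 <- BinaryMask(b4, spacing = c(1, 1, 1))
  a5 <- array(0L, c(5, 5, 5)); a5[2, 2, 4] <- 1L
  ma5 <- BinaryMask(a5, spacing = c(1, 1, 2))
  mb5 <- BinaryMask(b4, spacing = c(1, 1, 2))
  h2 <- hausdorff(ma5, mb5)
  expect_equal(h2$hd, 4)
  expect_equal(h2$hd95_paper, 3.8)
  expect_equal(assd(ma, ma), 0)
  expect_equal(hausdorff(ma, ma)$hd, 0)
  empty <- BinaryMask(array(0L, c(5, 5, 5)))
  expect_error(suppressWarnings(assd(ma, empty)), "empty")
})

test_that("surface distances agree with the all-pairs brute-force oracle", {
  set.seed(14)
  for (i in 1:25) {
    sp <- sample(c(1, 0.74, 1.25, 2), 3, replace = TRUE)
    pair <- randomMaskPair(c(7, 7, 7), spacing = sp)
    o <- oracleSurfDist(pair$a, pair$b)
    expect_equal(assd(pair$a, pair$b), o$assd, tolerance = 1e-9)
    h <- hausdorff(pair$a, pair$b)
    expect_equal(h$hd, o$hd, tolerance = 1e-9)
    expect_equal(h$hd95_percentile,
                 unname(quantile(o$pooled, 0.95, type = 7)), tolerance = 1e-9)
    expect_gte(h$hd, assd(pair$a, pair$b) - 1e-12)
    # symmetry
    expect_equal(assd(pair$b, pair$a), o$assd, tolerance = 1e-9)
    expect_equal(hausdorff(pair$b, pair$a)$hd, o$hd, tolerance = 1e-9)
  }
})

test_that("doubling the spacing doubles the surface distances exactly", {
  set.seed(15)
  pair <- randomMaskPair(c(7, 7, 7), spacing = c(1, 1, 1))
  a2 <- BinaryMask(voxelData(pair$a), spacing = c(2, 2, 2))
  b2 <- BinaryMask(voxelData(pair$b), spacing = c(2, 2, 2))
  expect_equal(assd(a2, b2), 2 * assd(pair$a, pair$b), tolerance = 1e-12)
  expect_equal(hausdorff(a2, b2)$hd, 2 * hausdorff(pair$a, pair$b)$hd,
               tolerance = 1e-12)
})

test_that("segmentation report ties the overlap and distance views together", {
  set.seed(16)
  pair <- randomMaskPair(c(8, 8, 8))
  r <- segmentationReport(pair$a, pair$b)
  expect_equal(r$dice, 2 * r$iou / (1 + r$iou), tolerance = 1e-10)
  expect_lte(r$assd_mm, r$hd_mm)
  expect_equal(r$hd95_paper_mm, 0.95 * r$hd_mm, tolerance = 1e-12)
  both <- BinaryMask(array(0L, c(4, 4, 4)))
  r0 <- suppressWarnings(segmentationReport(both, both))
  expect_equal(r0$dice, 1)
  expect_equal(r0$hd_mm, 0)
})

test_that("detection reporting counts hits and spurious predictions per instance", {
  # construct 10 truth instances on a 30^3 grid and 10 predictions,
  # 9 on-target and 1 spurious
  d <- c(30, 30, 30)
  lab <- array(0L, dim = d)
  centres <- expand.grid(z = c(5, 15, 25), y = c(5, 15, 25), x = c(5, 15))[1:10, ]
  for (r in 1:10)
    lab[centres$z[r] + (-1:1), centres$y[r] + (-1:1), centres$x[r] + (-1:1)] <-
      as.integer(1 + (r %% 4))
  truth <- LabelVolume(lab)
  pv <- array(0, dim = d)
  for (r in 1:9) pv[centres$z[r], centres$y[r], centres$x[r]] <- 0.9
  pv[28, 28, 28] <- 0.9                                   # spurious
  cs <- extractCandidates(ProbabilityVolume(pv), threshold = 0.5)
  rep <- detectionReport(cs, truth)
  expect_equal(rep$n_truth_instances, 10)
  expect_equal(rep$n_detected, 9)
  expect_equal(rep$n_false_positive_predictions, 1)
  expect_equal(rep$recognition_rate, 0.9)
  expect_equal(rep$fp_rate, 0.1)
  # exact truth components detect everything with no false positives
  csx <- extractCandidates(ProbabilityVolume(array(0.99 * (lab != 0), d)), 0.5)
  repx <- detectionReport(csx, truth)
  expect_equal(repx$recognition_rate, 1)
  expect_equal(repx$fp_rate, 0)
  # no accepted candidates
  rep0 <- detectionReport(csx, truth, accepted_ids = integer(0))
  expect_equal(rep0$recognition_rate, 0)
})
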