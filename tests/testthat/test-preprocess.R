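test_that("fingerprint spacing is the per-axis mean of sample spacings", {
  mk <- function(sp) {
    img <- ImageVolume(array(rnorm(27, 100, 10), c(3, 3, 3)), spacing = sp)
    lab <- LabelVolume(array(c(1L, rep(0L, 26)), c(3, 3, 3)), spacing = sp)
    list(image = img, labels = lab)
  }
  fp1 <- computeFingerprint(list(mk(c(2, 1, 1)), mk(c(2, 1, 1))))
  expect_equal(fp1$target_spacing, c(2, 1, 1))
  fp2 <- computeFingerprint(list(mk(c(1, 1, 1)), mk(c(3, 1, 1))))
  expect_equal(fp2$target_spacing, c(2, 1, 1))
})

test_that("clip bounds are foreground percentiles, matching a sort oracle", {
  # 1000 foreground voxels valued 0..999 uniformly
  vals <- array(0, c(10, 10, 10))
  vals[] <- 0:999
  img <- ImageVolume(vals)
  lab <- LabelVolume(array(1L, c(10, 10, 10)))
  fp <- computeFingerprint(list(list(image = img, labels = lab)))
  # linear-interpolation order statistics: q(p) = x[(n-1)p + 1]
  oracle <- function(p) {
    x <- sort(as.vector(vals))
    h <- (length(x) - 1) * p + 1
    lo <- floor(h)
    x[lo] + (h - lo) * (x[min(lo + 1, length(x))] - x[lo])
  }
  expect_equal(fp$hu_lo, oracle(0.005), tolerance = 1e-12)
  expect_equal(fp$hu_hi, oracle(0.995), tolerance = 1e-12)
  expect_equal(fp$hu_lo, 4.995)
  expect_equal(fp$hu_hi, 994.005)
})

test_that("fingerprinting fails loudly without any foreground", {
  img <- ImageVolume(array(rnorm(8), c(2, 2, 2)))
  lab <- LabelVolume(array(0L, c(2, 2, 2)))
  expect_error(computeFingerprint(list(list(image = img, labels = lab))),
               "foreground")
})

test_that("fingerprint JSON round-trips", {
  s <- generatePhantom(tinyPhantomConfig(), 0)
  fp <- computeFingerprint(list(s))
  f <- tempfile(fileext = ".json")
  writeFingerprint(fp, f)
  fp2 <- readFingerprint(f)
  expect_equal(fp2$target_spacing, fp$target_spacing)
  expect_equal(fp2$hu_lo, fp$hu_lo)
  unlink(f)
})

test_that("resampling preserves physical extent and follows the size formula", {
  img <- ImageVolume(array(rnorm(64^1 * 16 * 16), c(64, 16, 16)),
                     spacing = c(2, 2, 2))
  out <- resampleVolume(img, c(1, 1, 1))
  expect_equal(gridSize(out), as.integer(c(128, 32, 32)))
  # identity resampling returns the input voxels untouched
  same <- resampleVolume(img, c(2, 2, 2))
  expect_identical(voxelData(same), voxelData(img))
  # property: extent preserved within one new voxel per axis (random cases)
  set.seed(4)
  for (i in 1:20) {
    d <- sample(8:24, 3, replace = TRUE)
    os <- runif(3, 0.5, 3)
    ns <- runif(3, 0.5, 3)
    v <- ImageVolume(array(rnorm(prod(d)), d), spacing = os)
    r <- resampleVolume(v, ns)
    expect_true(all(abs(gridSize(r) * ns - d * os) <= ns + 1e-9))
  }
})

test_that("nearest-neighbour resampling never invents label values", {
  lab <- LabelVolume(array(sample(c(0L, 2L, -1L), 6 * 6 * 6, TRUE), c(6, 6, 6)),
                     spacing = c(1, 1, 1))
  out <- resampleVolume(lab, c(0.6, 0.6, 0.6))
  expect_s4_class(out, "LabelVolume")
  expect_true(all(voxelData(out) %in% c(0L, 2L, -1L)))
})

test_that("HU clipping saturates exactly at the bounds", {
  v <- array(c(-400, 0, 100, 251, 500, 700, 50, 150), c(2, 2, 2))
  img <- ImageVolume(v)
  out <- voxelData(clipHu(img, -100, 300))
  expect_equal(out, array(pmin(pmax(v, -100), 300), c(2, 2, 2)))
  # in-range data is untouched
  img2 <- ImageVolume(array(runif(27, 0, 1), c(3, 3, 3)))
  expect_identical(voxelData(clipHu(img2, -10, 10)), voxelData(img2))
  expect_error(clipHu(img, 10, 10), "hu_lo")
  # saturation law on random data
  set.seed(5)
  r <- array(rnorm(125, 0, 300), c(5, 5, 5))
  cl <- voxelData(clipHu(ImageVolume(r), -100, 200))
  expect_equal(min(cl), max(-100, min(r)))
  expect_equal(max(cl), min(200, max(r)))
})

test_that("z-scoring yields mean 0 / sd 1 and is affine-invariant", {
  set.seed(6)
  v <- array(rnorm(6^3, 40, 25), c(6, 6, 6))
  zn <- znormalize(ImageVolume(v))
  out <- voxelData(zn$image)
  expect_lt(abs(mean(out)), 1e-10)
  expect_lt(abs(sd(as.vector(out)) - 1), 1e-10)
  expect_equal(zn$stats$mean, mean(v))
  # idempotence: re-normalizing changes nothing (within fp tolerance)
  expect_equal(voxelData(znormalize(zn$image)$image), out, tolerance = 1e-10)
  # invariance under positive affine transforms of the input
  zn2 <- znormalize(ImageVolume(3.7 * v + 120))
  expect_equal(voxelData(zn2$image), out, tolerance = 1e-10)
  expect_error(znormalize(ImageVolume(array(5, c(3, 3, 3)))), "constant")
})

test_that("the preprocessing chain is resample -> clip -> normalize", {
  s <- generatePhantom(tinyPhantomConfig(), 0)
  fp <- computeFingerprint(list(s))
  pp <- preprocessSample(s, fp)
  out <- voxelData(pp$image)
  expect_lt(abs(mean(out)), 1e-10)
  expect_lt(abs(sd(as.vector(out)) - 1), 1e-10)
  # the mask is the merged, nearest-resampled label volume
  expect_true(all(voxelData(pp$mask) %in% c(0L, 1L)))
  expect_identical(gridSize(pp$mask), gridSize(pp$image))
  # clipping happened before normalization: reconstructed HU range is bounded
  hu <- out * pp$stats$std + pp$stats$mean
  expect_gte(min(hu), fp$hu_lo - 1e-6)
  expect_lte(max(hu), fp$hu_hi + 1e-6)
})
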