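test_that("configurations enforce divisibility and rank", {
  expect_error(unetConfig(3, c(30, 32, 32), c(2, 2, 2)), "divisible")
  expect_error(unetConfig(2, c(32, 32, 32), c(2, 2, 2)), "2-vector")
  cfg <- unetConfig(2, c(64, 64), c(3, 3))
  expect_equal(cfg$patch_size, as.integer(c(1, 64, 64)))
  # full-scale presets construct and carry the printed geometry
  p3 <- unetPreset("paper_3d_fullres")
  expect_equal(p3$patch_size, as.integer(c(96, 160, 160)))
  expect_equal(p3$pools_per_axis, as.integer(c(4, 5, 5)))
  p2 <- unetPreset("paper_2d")
  expect_equal(p2$pools_per_axis, as.integer(c(0, 7, 7)))
})

test_that("the segmenter maps patches to same-shape probabilities, seeded", {
  cfg <- unetConfig(3, c(8, 8, 8), c(1, 1, 1), base_channels = 2)
  m1 <- buildSegmenter(cfg, seed = 42)
  m2 <- buildSegmenter(cfg, seed = 42)
  m3 <- buildSegmenter(cfg, seed = 43)
  x <- array(rnorm(8^3), c(8, 8, 8))
  p1 <- predictPatch(m1, x)
  expect_equal(dim(p1), c(8, 8, 8))
  expect_true(all(p1 >= 0 & p1 <= 1))
  expect_identical(p1, predictPatch(m2, x))            # same seed, same net
  expect_false(identical(p1, predictPatch(m3, x)))
  # 2D variant accepts single-slice patches
  cfg2 <- unetConfig(2, c(16, 16), c(2, 2), base_channels = 2)
  m2d <- buildSegmenter(cfg2, seed = 1)
  p2d <- predictPatch(m2d, array(rnorm(16 * 16), c(1, 16, 16)))
  expect_equal(dim(p2d), c(1, 16, 16))
  expect_error(predictPatch(m1, array(0, c(4, 4, 4))), "patch")
})

test_that("patch sampling oversamples foreground and pads small volumes", {
  s <- list(image = ImageVolume(array(rnorm(16^3), c(16, 16, 16))),
            mask = BinaryMask(local({
              m <- array(0L, c(16, 16, 16)); m[9, 9, 9] <- 1L; m
            })))
  set.seed(17)
  for (i in 1:20) {
    pt <- samplePatch(s, c(8, 8, 8), fg_fraction = 1)
    expect_gte(sum(pt$mask), 1)
  }
  # fraction 0: origins uniform on the valid range (chi-square, 1000 draws)
  set.seed(18)
  origins <- replicate(1000, samplePatch(s, c(8, 8, 8), fg_fraction = 0)$origin[1])
  tab <- tabulate(origins, nbins = 9)
  pval <- stats::chisq.test(tab)$p.value
  expect_gt(pval, 0.01)
  # a volume smaller than the patch is padded; mask padding is background
  small <- list(image = ImageVolume(array(rnorm(4^3) + 10, c(4, 4, 4))),
                mask = BinaryMask(array(1L, c(4, 4, 4))))
  pt <- samplePatch(small, c(8, 8, 8), fg_fraction = 0)
  expect_equal(dim(pt$image), c(8, 8, 8, 1))
  expect_equal(sum(pt$mask), 64)                       # original foreground only
})

test_that("training is seeded, records history, and aborts sanely", {
  s <- generatePhantom(tinyPhantomConfig(), 0)
  pp <- preprocessSample(s, computeFingerprint(list(s)))
  cfg <- unetConfig(3, c(8, 8, 8), c(1, 1, 1), base_channels = 2)
  tc0 <- trainConfig(epochs = 0, seed = 3)
  r0 <- trainSegmenter(list(pp), cfg, tc0)
  expect_equal(nrow(r0$history), 0L)
  tc <- trainConfig(batch_size = 1, epochs = 3, steps_per_epoch = 2, seed = 3)
  r <- trainSegmenter(list(pp), cfg, tc)
  expect_equal(nrow(r$history), 3L)
  expect_true(all(is.finite(r$history$total)))
  expect_named(r$history, c("epoch", "l_dice", "l_ce", "l_contour", "total"))
  r2 <- trainSegmenter(list(pp), cfg, tc)
  expect_equal(r$history, r2$history)                  # fully reproducible
  expect_error(trainSegmenter(list(), cfg, tc), "empty")
})

test_that("a tiny 3D model learns a separable toy task to Dice >= 0.6", {
  # bright noiseless blobs on a flat background: linearly separable
  mk <- function(seed) {
    cfgp <- phantomConfig(grid_size = c(32, 32, 32), spacing_mm = c(1, 1, 1),
                          n_ribs = 1, n_lesions = 2,
                          lesion_radius_mm = c(3, 5), hu_background = 0,
                          hu_bone = 0, hu_lesion = 500, noise_sd = 0,
                          uncertain_fraction = 0, seed = seed)
    s <- generatePhantom(cfgp, 0)
    list(image = ImageVolume(voxelData(phantomImage(s)) / 250 - 1,
                             geometry = geometry(phantomImage(s))),
         mask = mergeLabels(phantomLabels(s)))
  }
  pre <- lapply(1:4, mk)
  cfg <- unetConfig(3, c(16, 16, 16), c(2, 2, 2), base_channels = 4)
  tc <- trainConfig(batch_size = 2, epochs = 30, learning_rate = 1e-3,
                    fg_patch_fraction = 0.5, steps_per_epoch = 10, seed = 3)
  seg <- trainSegmenter(pre, cfg, tc)
  set.seed(5)
  dice <- replicate(10, {
    pt <- samplePatch(pre[[sample.int(4, 1)]], c(16, 16, 16), 1)
    pm <- (predictPatch(seg$model, pt$image) > 0.5) * 1
    2 * sum(pm * pt$mask) / (sum(pm) + sum(pt$mask) + 1e-9)
  })
  expect_gte(mean(dice), 0.6)
})

test_that("the cascade wires the coarse probability into the fine model", {
  expect_error(
    cascadeConfig(c(2, 2, 2), unetConfig(3, c(8, 8, 8), c(1, 1, 1), 2),
                  unetConfig(3, c(8, 8, 8), c(1, 1, 1), 2)),
    "2 input channels")
  cc <- cascadeConfig(c(2.5, 1.48, 1.48),
                      coarse = unetConfig(3, c(8, 8, 8), c(1, 1, 1), 2),
                      fine = unetConfig(3, c(8, 8, 8), c(1, 1, 1), 2,
                                        in_channels = 2))
  s <- generatePhantom(tinyPhantomConfig(), 0)
  pp <- preprocessSample(s, computeFingerprint(list(s)))
  tc <- trainConfig(batch_size = 1, epochs = 2, steps_per_epoch = 2, seed = 3)
  cas <- trainCascade(list(pp), cc, tc)
  expect_equal(cas$fine$cfg$in_channels, 2L)
  expect_true(all(is.finite(cas$fine_history$total)))
  expect_true(all(is.finite(cas$coarse_history$total)))
  # fine prediction consumes image + coarse probability over a whole volume
  plan <- planWindows(geometry(pp$image), c(8, 8, 8), 0.25)
  extra <- ProbabilityVolume(array(0.5, dim(voxelData(pp$image))),
                             geometry = geometry(pp$image))
  f <- predictVolume(cas$fine, pp$image, plan, extra = extra)
  expect_true(all(f$values >= 0 & f$values <= 1))
})
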