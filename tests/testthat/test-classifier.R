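test_that("the dense classifier maps crops to seeded probabilities", {
  cfg <- denseNetConfig(8, growth_rate = 4, block_layout = c(2, 2))
  m1 <- buildClassifier(cfg, seed = 7)
  m2 <- buildClassifier(cfg, seed = 7)
  x <- array(rnorm(8^3), c(8, 8, 8))
  p <- classifierProb(m1, x)
  expect_gte(p, 0)
  expect_lte(p, 1)
  expect_identical(p, classifierProb(m2, x))
  expect_error(classifierProb(m1, array(0, c(6, 6, 6))), "input size")
  expect_error(denseNetConfig(9, block_layout = c(2, 2)), "divisible")
})

test_that("dense connectivity grows channels as input + layers x growth", {
  g <- 5L
  cfg <- denseNetConfig(8, growth_rate = g, block_layout = c(3, 2))
  m <- buildClassifier(cfg, seed = 1)
  fw <- fracturekit:::.densenetForward(m, array(rnorm(8^3), c(8, 8, 8)),
                                       keep_cache = TRUE)
  stem_ch <- 2L * g
  # input channels of layer j in block 1: stem + (j-1) * growth
  for (j in 1:3)
    expect_equal(dim(fw$cache$blocks[[1]][[j]]$x)[4], stem_ch + (j - 1L) * g)
  after_block1 <- stem_ch + 3L * g
  trans_out <- floor(after_block1 * cfg$compression)
  expect_equal(dim(fw$cache$blocks[[2]][[1]]$x)[4], trans_out)
  expect_equal(dim(fw$cache$final_in)[4], trans_out + 2L * g)
})

test_that("candidate labelling is overlap with truth, verified by intersection", {
  pv <- array(0, c(12, 12, 12))
  pv[2:4, 2:4, 2:4] <- 0.9
  pv[9:11, 9:11, 9:11] <- 0.9
  cs <- extractCandidates(ProbabilityVolume(pv), 0.5)
  tm <- array(0L, c(12, 12, 12))
  tm[3:5, 3:5, 3:5] <- 1L                              # overlaps first blob only
  truth <- BinaryMask(tm)
  tab <- labelCandidates(cs, truth)
  lm <- componentMap(cs)
  for (r in seq_len(nrow(tab))) {
    id <- tab$component_id[r]
    brute <- as.integer(sum(tm[lm == id]) > 0)         # set intersection
    expect_equal(tab$label[r], brute)
  }
  expect_equal(sum(tab$label), 1L)
  wrong <- BinaryMask(array(0L, c(6, 6, 6)))
  expect_error(labelCandidates(cs, wrong), "geometry")
})

test_that("probability fusion is a normalized weighted average", {
  w <- list(lambda1 = 0.9, lambda2 = 0.8, lambda3 = 0.7)
  expect_equal(fuseProbabilities(w, 0.6, 0.5, 0.4),
               (0.54 + 0.40 + 0.28) / 2.4, tolerance = 1e-12)
  expect_equal(round(fuseProbabilities(w, 0.6, 0.5, 0.4), 4), 0.5083)
  expect_equal(fuseProbabilities(list(lambda1 = 1, lambda2 = 0, lambda3 = 0),
                                 0.37, 0.9, 0.1), 0.37)
  expect_equal(fuseProbabilities(w, 0.42, 0.42, 0.42), 0.42, tolerance = 1e-12)
  expect_error(fuseProbabilities(list(lambda1 = 0, lambda2 = 0, lambda3 = 0),
                                 0.5, 0.5, 0.5), "sum")
  # the literal unnormalized form can exceed 1
  expect_equal(fuseProbabilities(list(lambda1 = 1, lambda2 = 1, lambda3 = 1),
                                 0.9, 0.9, 0.9, normalize = FALSE), 2.7)
  # bounded by [min, max] of the inputs for random weights/probabilities
  set.seed(23)
  for (i in 1:50) {
    l <- runif(3); p <- runif(3)
    f <- fuseProbabilities(list(lambda1 = l[1], lambda2 = l[2], lambda3 = l[3]),
                           p[1], p[2], p[3])
    expect_gte(f, min(p) - 1e-12)
    expect_lte(f, max(p) + 1e-12)
  }
})

test_that("the ensemble trains per size and weights by validation accuracy", {
  # linearly separable synthetic crops: bright central blob = positive
  set.seed(24)
  sizes <- c(8L, 10L, 12L)
  n <- 28
  labels <- rep(c(1L, 0L), length.out = n)
  crops <- lapply(seq_len(n), function(i) {
    lapply(sizes, function(s) {
      x <- array(rnorm(s^3, 0, 0.5), c(s, s, s))
      if (labels[i] == 1L) {
        c0 <- s %/% 2
        x[(c0 - 1):(c0 + 1), (c0 - 1):(c0 + 1), (c0 - 1):(c0 + 1)] <-
          x[(c0 - 1):(c0 + 1), (c0 - 1):(c0 + 1), (c0 - 1):(c0 + 1)] + 3
      }
      x
    })
  })
  configs <- lapply(sizes, function(s) denseNetConfig(s, growth_rate = 4))
  tc <- trainConfig(batch_size = 2, epochs = 8, learning_rate = 5e-3, seed = 5)
  ens <- trainClassifierEnsemble(crops, labels, configs, tc)
  expect_gte(ens$weights$lambda1, 0.9)
  expect_gte(ens$weights$lambda2, 0.9)
  expect_gte(ens$weights$lambda3, 0.9)
  # decisions: reproducible, thresholds behave as decision boundaries
  dec <- classifyCandidates(ens, crops, threshold = 0.5,
                            candidate_ids = seq_len(n))
  dec2 <- classifyCandidates(ens, crops, threshold = 0.5,
                             candidate_ids = seq_len(n))
  expect_equal(dec, dec2)
  expect_true(all(classifyCandidates(ens, crops, threshold = 0)$label == 1L))
  dec1 <- classifyCandidates(ens, crops, threshold = 1)
  expect_true(all(dec1$label[dec1$p_fused < 1] == 0L))
  # fused decisions recover the separable labels well
  expect_gte(mean(dec$label == labels), 0.85)
  expect_error(trainClassifierEnsemble(crops, rep(1L, n), configs, tc),
               "degenerate")
})
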