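test_that("window planning enumerates clamped strided origins with full coverage", {
  p1 <- planWindows(c(8, 8, 8), c(8, 8, 8), 0.5)
  expect_equal(nrow(p1$origins), 1L)
  expect_equal(unname(p1$origins[1, ]), c(1, 1, 1))
  # axis 10, patch 4, overlap 0.5 (stride 2): origins 1,3,5,7 per axis
  p2 <- planWindows(c(10, 10, 10), c(4, 4, 4), 0.5)
  expect_equal(sort(unique(p2$origins[, 1])), c(1, 3, 5, 7))
  expect_error(planWindows(c(10, 10, 10), c(4, 4, 4), 1), "overlap")
  # coverage: every voxel inside >= 1 window, all windows inside the volume
  set.seed(19)
  for (i in 1:20) {
    vol <- sample(6:20, 3, replace = TRUE)
    patch <- pmin(vol, sample(3:8, 3, replace = TRUE))
    ov <- runif(1, 0, 0.8)
    pl <- planWindows(vol, patch, ov)
    covered <- array(FALSE, dim = pl$vol_size)
    for (r in seq_len(nrow(pl$origins))) {
      o <- pl$origins[r, ]
      expect_true(all(o >= 1) && all(o + patch - 1 <= pl$vol_size))
      covered[o[1]:(o[1] + patch[1] - 1), o[2]:(o[2] + patch[2] - 1),
              o[3]:(o[3] + patch[3] - 1)] <- TRUE
    }
    expect_true(all(covered))
  }
})

test_that("max fusion takes the per-voxel maximum over windows", {
  img <- ImageVolume(array(rnorm(6^3), c(6, 6, 6)))
  plan <- planWindows(c(6, 6, 6), c(4, 4, 4), 0.5)
  # constant operator: fused volume is that constant, counts >= 1
  fc <- predictVolume(function(p) array(0.3, dim(p)[1:3]), img, plan)
  expect_true(all(fc$values == 0.3))
  expect_true(all(fc$counts >= 1))
  # two overlapping windows returning 0.2 then 0.7: shared voxels read 0.7
  plan2 <- planWindows(c(6, 4, 4), c(4, 4, 4), 0.5)
  img2 <- ImageVolume(array(0, c(6, 4, 4)))
  counter <- local({ k <- 0; function(p) { k <<- k + 1; array(c(0.2, 0.7)[k], dim(p)[1:3]) } })
  f2 <- predictVolume(counter, img2, plan2)
  expect_equal(f2$values[3, 1, 1], 0.7)                # overlap region
  expect_equal(f2$values[1, 1, 1], 0.2)                # first window only
  expect_equal(f2$counts[3, 1, 1], 2L)
  # mean fusion averages instead
  counter2 <- local({ k <- 0; function(p) { k <<- k + 1; array(c(0.2, 0.7)[k], dim(p)[1:3]) } })
  fm <- predictVolume(counter2, img2, plan2, fusion = "mean")
  expect_equal(fm$values[3, 1, 1], 0.45)
})

test_that("fused output equals a brute-force accumulation oracle", {
  set.seed(20)
  for (trial in 1:10) {
    vol <- sample(6:12, 3, replace = TRUE)
    patch <- pmin(vol, c(4, 4, 4))
    img <- ImageVolume(array(rnorm(prod(vol)), vol))
    plan <- planWindows(vol, patch, runif(1, 0, 0.6))
    recorded <- list()
    op <- function(p) {
      out <- array(runif(prod(dim(p)[1:3])), dim(p)[1:3])
      recorded[[length(recorded) + 1L]] <<- out
      out
    }
    f <- predictVolume(op, img, plan)
    acc <- array(-Inf, dim = plan$vol_size)
    for (r in seq_len(nrow(plan$origins))) {
      o <- plan$origins[r, ]
      zi <- o[1]:(o[1] + patch[1] - 1); yi <- o[2]:(o[2] + patch[2] - 1)
      xi <- o[3]:(o[3] + patch[3] - 1)
      acc[zi, yi, xi] <- pmax(acc[zi, yi, xi], recorded[[r]])
    }
    expect_equal(f$values, acc[1:vol[1], 1:vol[2], 1:vol[3], drop = FALSE])
    # fused >= any single window's value at shared voxels (spot check window 1)
    o <- plan$origins[1, ]
    expect_true(all(f$values[o[1]:(o[1] + patch[1] - 1),
                             o[2]:(o[2] + patch[2] - 1),
                             o[3]:(o[3] + patch[3] - 1)] >= recorded[[1]] - 1e-12))
  }
})

test_that("candidate extraction matches a flood-fill oracle and filters by size", {
  pv <- array(0, c(12, 12, 12))
  pv[2:3, 2:3, 2:3] <- 0.9                             # 8 voxels
  pv[8:10, 8:10, 8:10] <- 0.8                          # 27 voxels
  cs <- extractCandidates(ProbabilityVolume(pv), 0.5)
  tab <- candidateTable(cs)
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$voxel_count, c(27L, 8L))            # sorted by size
  expect_equal(tab$mean_probability, c(0.8, 0.9))
  # min size filter
  expect_equal(nrow(candidateTable(
    extractCandidates(ProbabilityVolume(pv), 0.5, min_component_size = 30))), 0L)
  # nothing above threshold
  expect_equal(nrow(candidateTable(
    extractCandidates(ProbabilityVolume(pv * 0.1), 0.5))), 0L)
  expect_error(extractCandidates(ProbabilityVolume(pv), 0), "threshold")
  # random volumes against the BFS oracle (both connectivities)
  set.seed(21)
  for (trial in 1:30) {
    conn <- sample(c(6, 26), 1)
    p <- array(runif(10^3), c(10, 10, 10))
    cs <- extractCandidates(ProbabilityVolume(p), 0.7, connectivity = conn)
    ff <- oracleFloodFill(p > 0.7, connectivity = conn)
    tab <- candidateTable(cs)
    expect_equal(nrow(tab), max(ff))
    expect_equal(sort(tab$voxel_count), sort(as.integer(table(ff[ff > 0]))))
  }
})

test_that("multi-scale crops share a centre and pad out-of-bounds regions", {
  set.seed(22)
  img <- ImageVolume(array(rnorm(24^3, 10, 2), c(24, 24, 24)))
  centre <- list(component_id = 1L, z_c = 12, y_c = 12, x_c = 12)
  ms <- cropMultiscale(img, centre, c(8, 12, 16))
  expect_equal(lapply(ms$crops, dim),
               list(rep(8L, 3), rep(12L, 3), rep(16L, 3)))
  # no padding when the candidate is deep inside: crops are plain subarrays
  expect_equal(ms$crops[[3]], voxelData(img)[4:19, 4:19, 4:19])
  # nested crops agree on their shared central region
  inner_in_mid <- ms$crops[[2]][3:10, 3:10, 3:10]
  expect_equal(inner_in_mid, ms$crops[[1]])
  mid_in_outer <- ms$crops[[3]][3:14, 3:14, 3:14]
  expect_equal(mid_in_outer, ms$crops[[2]])
  # at the corner the crop keeps its shape; padded voxels carry the fill value
  corner <- list(component_id = 2L, z_c = 1, y_c = 1, x_c = 1)
  mc <- cropMultiscale(img, corner, c(8, 12, 16))
  expect_equal(dim(mc$crops[[1]]), rep(8L, 3))
  expect_equal(mc$crops[[1]][1, 1, 1], min(voxelData(img)))
  expect_error(cropMultiscale(img, centre, c(8, 8, 16)), "increasing")
})
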