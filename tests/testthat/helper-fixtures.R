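# Shared fixtures and independent oracles for the test suite.  Oracles are
# deliberately naive (voxel loops, all-pairs distances, BFS flood fill) and
# never call the implementation paths they check.

# small, fast phantom world for unit tests; any field overridable via ...
tinyPhantomConfig <- function(..., seed = 11) {
  defaults <- list(grid_size = c(32, 32, 32), spacing_mm = c(1.25, 0.74, 0.74),
                   n_ribs = 2, n_lesions = 2, lesion_radius_mm = c(2, 3.5),
                   noise_sd = 20, seed = seed)
  do.call(phantomConfig, utils::modifyList(defaults, list(...)))
}

# a random binary mask volume with blob-ish structure
randomMask <- function(dims = c(12, 12, 12), p = 0.15,
                       spacing = c(1, 1, 1)) {
  v <- array(as.integer(runif(prod(dims)) < p), dim = dims)
  BinaryMask(v, spacing = spacing)
}

# --- brute-force oracles ---------------------------------------------------

# 26- or 6-connectivity flood fill, plain R BFS
oracleFloodFill <- function(mask, connectivity = 26) {
  d <- dim(mask)
  lab <- array(0L, dim = d)
  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  nextid <- 0L
  for (ii in which(mask != 0)) {
    if (lab[ii] != 0L) next
    nextid <- nextid + 1L
    queue <- ii
    lab[ii] <- nextid
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      cc <- arrayInd(cur, d)[1, ]
      for (k in seq_len(nrow(offs))) {
        nb <- cc + offs[k, ]
        if (any(nb < 1) || any(nb > d)) next
        if (mask[nb[1], nb[2], nb[3]] != 0 && lab[nb[1], nb[2], nb[3]] == 0L) {
          lab[nb[1], nb[2], nb[3]] <- nextid
          queue <- c(queue, nb[1] + d[1] * (nb[2] - 1L) + d[1] * d[2] * (nb[3] - 1L))
        }
      }
    }
  }
  lab
}

# surface voxels per the 6-neighbour/border definition, plain loops
oracleSurface <- function(mask) {
  m <- voxelData(mask)
  d <- dim(m)
  sp <- spacingMm(mask)
  pts <- NULL
  for (z in seq_len(d[1])) for (y in seq_len(d[2])) for (x in seq_len(d[3])) {
    if (m[z, y, x] != 1L) next
    nb <- rbind(c(z - 1, y, x), c(z + 1, y, x), c(z, y - 1, x),
                c(z, y + 1, x), c(z, y, x - 1), c(z, y, x + 1))
    on_surf <- FALSE
    for (k in 1:6) {
      q <- nb[k, ]
      if (any(q < 1) || any(q > d) || m[q[1], q[2], q[3]] == 0L) {
        on_surf <- TRUE
        break
      }
    }
    if (on_surf) pts <- rbind(pts, (c(z, y, x) - 1) * sp)
  }
  pts
}

# all-pairs symmetric surface distances
oracleSurfDist <- function(pred, truth) {
  A <- oracleSurface(pred)
  B <- oracleSurface(truth)
  D <- outer(seq_len(nrow(A)), seq_len(nrow(B)), Vectorize(function(i, j)
    sqrt(sum((A[i, ] - B[j, ])^2))))
  dab <- apply(D, 1, min)
  dba <- apply(D, 2, min)
  list(assd = (sum(dab) + sum(dba)) / (nrow(A) + nrow(B)),
       hd = max(max(dab), max(dba)),
       pooled = c(dab, dba))
}

# a random nonempty mask pair on a shared small grid
randomMaskPair <- function(dims = c(10, 10, 10), spacing = c(1, 1, 1)) {
  repeat {
    a <- randomMask(dims, p = runif(1, 0.05, 0.3), spacing = spacing)
    b <- randomMask(dims, p = runif(1, 0.05, 0.3), spacing = spacing)
    if (sum(voxelData(a)) > 0 && sum(voxelData(b)) > 0) return(list(a = a, b = b))
  }
}

# --- shared end-to-end run for the acceptance suite ------------------------
# criteria 5 and 6 both consume the same seeded pipeline run; cache it
.e2e_cache <- new.env(parent = emptyenv())

acceptancePipelineRun <- function() {
  if (is.null(.e2e_cache$manifest)) {
    wd <- file.path(tempdir(), "fk-acceptance-run")
    .e2e_cache$manifest <- runPipeline(tinyPipelineConfig(seed = 1), wd)
  }
  .e2e_cache$manifest
}
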