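# Whole-volume prediction: tile the volume with overlapping patches, predict
# each, and fuse overlaps by the per-voxel maximum; then threshold, extract
# connected components as candidate regions, and harvest multi-scale crops
# around each candidate for the stage-2 classifiers.

#' Plan sliding windows over a volume
#'
#' Window origins lie on a regular grid with stride
#' `round(patch * (1 - overlap))` per axis (at least 1); the last origin is
#' clamped so the final window abuts the volume edge.  Every voxel is covered
#' by at least one window and all windows lie fully inside the (padded)
#' volume.  Volumes smaller than the patch are planned at the padded size.
#'
#' @param geom a [VolumeGeometry-class], or integer(3) volume size.
#' @param patch_size integer(3) patch size (z, y, x).
#' @param overlap fraction in `[0, 1)` of patch overlap between neighbours.
#' @return list of class `SlidingWindowPlan` with `patch_size`, `overlap`,
#'   `vol_size` (padded), `orig_size`, and `origins` (matrix, one 1-based
#'   window origin per row).
#' @export
planWindows <- function(geom, patch_size, overlap = 0.5) {
  size <- if (is(geom, "VolumeGeometry")) geom@size else as.integer(geom)
  patch_size <- as.integer(patch_size)
  if (overlap < 0 || overlap >= 1) stop("overlap must lie in [0, 1)")
  padded <- pmax(size, patch_size)
  stride <- pmax(1L, as.integer(round(patch_size * (1 - overlap))))
  ax <- lapply(1:3, function(a) {
    last <- padded[a] - patch_size[a] + 1L
    o <- unique(c(seq.int(1L, last, by = stride[a]), last))
    sort(o)
  })
  origins <- as.matrix(expand.grid(z = ax[[1]], y = ax[[2]], x = ax[[3]]))
  structure(list(patch_size = patch_size, overlap = overlap,
                 vol_size = padded, orig_size = size, origins = origins),
            class = "SlidingWindowPlan")
}

#' Sliding-window whole-volume prediction with max fusion
#'
#' Runs the operator over every planned window and fuses overlapping
#' predictions per voxel by taking the maximum (optionally the mean), also
#' recording how many windows contributed to each voxel.  Volumes smaller
#' than the patch are padded with the image minimum (extra channel: 0) and
#' cropped back.
#'
#' @param operator a `Segmenter`, or a function mapping a 4D patch array
#'   `(z, y, x, channel)` to a 3D probability array.
#' @param image preprocessed [ImageVolume-class].
#' @param plan a [planWindows()] plan matching the operator patch size.
#' @param extra optional [ProbabilityVolume-class] appended as a second input
#'   channel (cascade fine stage).
#' @param fusion `"max"` (the default, as in the two-stage recognition
#'   pipeline) or `"mean"` for comparison.
#' @return list of class `FusedProbability` with `values` (3D array in
#'   `[0, 1]`), `counts` (windows per voxel, >= 1) and `geometry`.
#' @export
predictVolume <- function(operator, image, plan, extra = NULL,
                          fusion = c("max", "mean")) {
  fusion <- match.arg(fusion)
  stopifnot(inherits(plan, "SlidingWindowPlan"), is(image, "ImageVolume"))
  op <- if (inherits(operator, "Segmenter")) {
    if (!identical(operator$cfg$patch_size, plan$patch_size))
      stop("plan patch size does not match operator patch size")
    function(patch) .unetForward(operator, patch)$prob
  } else operator
  img <- voxelData(image)
  d <- dim(img)
  if (!identical(as.integer(d), plan$orig_size))
    stop("plan was made for a different volume size")
  ps <- plan$patch_size
  vol <- .cropPad(img, c(1L, 1L, 1L), plan$vol_size, min(img))
  chans <- if (is.null(extra)) {
    array(vol, dim = c(plan$vol_size, 1L))
  } else {
    ev <- .cropPad(voxelData(extra), c(1L, 1L, 1L), plan$vol_size, 0)
    array(c(vol, ev), dim = c(plan$vol_size, 2L))
  }
  acc <- array(if (fusion == "max") -Inf else 0, dim = plan$vol_size)
  counts <- array(0L, dim = plan$vol_size)
  for (i in seq_len(nrow(plan$origins))) {
    o <- plan$origins[i, ]
    zi <- o[1]:(o[1] + ps[1] - 1L)
    yi <- o[2]:(o[2] + ps[2] - 1L)
    xi <- o[3]:(o[3] + ps[3] - 1L)
    pr <- op(chans[zi, yi, xi, , drop = FALSE])
    if (fusion == "max") {
      acc[zi, yi, xi] <- pmax(acc[zi, yi, xi], pr)
    } else {
      acc[zi, yi, xi] <- acc[zi, yi, xi] + pr
    }
    counts[zi, yi, xi] <- counts[zi, yi, xi] + 1L
  }
  if (fusion == "mean") acc <- acc / pmax(counts, 1L)
  s <- plan$orig_size
  structure(list(values = acc[1:s[1], 1:s[2], 1:s[3], drop = FALSE],
                 counts = counts[1:s[1], 1:s[2], 1:s[3], drop = FALSE],
                 geometry = if (is(image, "Volume")) geometry(image) else NULL),
            class = "FusedProbability")
}

#' Extract candidate regions from a fused probability volume
#'
#' Binarizes at `threshold`, labels connected components under the stated
#' connectivity, discards components smaller than `min_component_size`, and
#' summarizes each surviving component (voxel count, bounding box, centroid,
#' mean probability).  Candidates are sorted by decreasing voxel count, ties
#' by component id.
#'
#' @param fused a `FusedProbability` (from [predictVolume()]) or a
#'   [ProbabilityVolume-class].
#' @param threshold binarization threshold in `(0, 1)`.
#' @param connectivity 6 or 26.
#' @param min_component_size minimum voxel count, default 1 (no filtering).
#' @return a [CandidateSet-class].
#' @export
extractCandidates <- function(fused, threshold = 0.5, connectivity = 26,
                              min_component_size = 1) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must lie in (0, 1)")
  if (!connectivity %in% c(6, 26)) stop("connectivity must be 6 or 26")
  vals <- if (is(fused, "Volume")) voxelData(fused) else fused$values
  geom <- if (is(fused, "Volume")) geometry(fused) else fused$geometry
  if (is.null(geom)) geom <- VolumeGeometry(dim(vals))
  d <- dim(vals)
  mask <- array(as.integer(vals > threshold), dim = d)
  lab <- .label_components(mask, d, as.integer(connectivity))
  tab <- data.frame(component_id = integer(0), voxel_count = integer(0),
                    z_min = integer(0), z_max = integer(0),
                    y_min = integer(0), y_max = integer(0),
                    x_min = integer(0), x_max = integer(0),
                    z_c = numeric(0), y_c = numeric(0), x_c = numeric(0),
                    mean_probability = numeric(0))
  k <- max(lab)
  if (k > 0L) {
    idx <- which(lab > 0L)
    co <- arrayInd(idx, d)
    ids <- lab[idx]
    for (comp in seq_len(k)) {
      sel <- ids == comp
      n <- sum(sel)
      if (n < min_component_size) next
      cc <- co[sel, , drop = FALSE]
      tab[nrow(tab) + 1L, ] <- list(comp, n,
        min(cc[, 1]), max(cc[, 1]), min(cc[, 2]), max(cc[, 2]),
        min(cc[, 3]), max(cc[, 3]),
        mean(cc[, 1]), mean(cc[, 2]), mean(cc[, 3]),
        mean(vals[idx[sel]]))
    }
    if (nrow(tab))
      tab <- tab[order(-tab$voxel_count, tab$component_id), , drop = FALSE]
    rownames(tab) <- NULL
  }
  new("CandidateSet", labelmap = lab, table = tab, geometry = geom,
      threshold = threshold)
}

#' Harvest multi-scale crops around a candidate
#'
#' Clips cubic sub-volumes of the given edge lengths (default 48, 64 and 80
#' voxels of the preprocessed grid), all centred on the candidate centroid
#' (rounded down); regions outside the volume are padded with the image
#' minimum, so every crop has exactly the requested shape.
#'
#' @param image preprocessed [ImageVolume-class].
#' @param candidate one row of a [candidateTable()] (or any list with
#'   `z_c`, `y_c`, `x_c`).
#' @param sizes strictly increasing cubic edge lengths, each >= 8.
#' @return list of class `MultiScaleCrops` with `sizes`, `crops` (list of 3D
#'   arrays) and `candidate_id`.
#' @export
cropMultiscale <- function(image, candidate, sizes = c(48, 64, 80)) {
  sizes <- as.integer(sizes)
  if (any(diff(sizes) <= 0) || any(sizes < 8L))
    stop("sizes must be strictly increasing and >= 8")
  img <- voxelData(image)
  fill <- min(img)
  cen <- floor(c(candidate$z_c, candidate$y_c, candidate$x_c))
  crops <- lapply(sizes, function(s) {
    origin <- as.integer(cen - s %/% 2L)
    .cropPad(img, origin, rep(s, 3L), fill)
  })
  structure(list(sizes = sizes, crops = crops,
                 candidate_id = candidate$component_id %||% NA_integer_),
            class = "MultiScaleCrops")
}
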