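# Fingerprint-driven preprocessing: resample every volume to the dataset's
# mean voxel spacing, clip intensities to the [0.5, 99.5] percentiles of the
# pooled foreground HU values, then z-score each sample.  The order
# (resample -> clip -> normalize) is fixed.

.sampleImage <- function(s) if (is(s, "PhantomSample")) s@image else s$image
.sampleLabels <- function(s) if (is(s, "PhantomSample")) s@labels else s$labels

#' Compute a dataset fingerprint
#'
#' The fingerprint drives preprocessing: `target_spacing` is the per-axis
#' arithmetic mean of the training samples' spacings (the common grid all
#' volumes are resampled to); `hu_lo`/`hu_hi` are the 0.5th and 99.5th
#' percentiles of the Hounsfield values pooled over all foreground voxels
#' (voxels whose merged label is 1) of the dataset; `median_size` is the
#' per-axis median of the resampled volume sizes.
#'
#' Percentiles use linear interpolation between order statistics
#' (`stats::quantile` type 7).
#'
#' @param samples list of [PhantomSample-class] objects, or of lists with
#'   `$image` ([ImageVolume-class]) and `$labels` ([LabelVolume-class]).
#' @param target_spacing optional override of the computed mean spacing.
#' @return list of class `DatasetFingerprint` with fields `target_spacing`,
#'   `hu_lo`, `hu_hi`, `median_size`.
#' @export
computeFingerprint <- function(samples, target_spacing = NULL) {
  if (!length(samples)) stop("need at least one sample")
  spac <- t(vapply(samples, function(s) spacingMm(.sampleImage(s)), numeric(3)))
  if (is.null(target_spacing)) target_spacing <- colMeans(spac)
  if (any(target_spacing <= 0)) stop("target spacing must be positive")
  fg <- unlist(lapply(samples, function(s) {
    img <- .sampleImage(s); lab <- .sampleLabels(s)
    v <- voxelData(img)[voxelData(mergeLabels(lab)) == 1L]
    v
  }))
  if (!length(fg))
    stop("no foreground voxels in any sample; cannot fingerprint intensities")
  q <- unname(quantile(fg, c(0.005, 0.995), type = 7))
  sizes <- t(vapply(seq_along(samples), function(i) {
    g <- geometry(.sampleImage(samples[[i]]))
    pmax(1, round(g@size * g@spacing / target_spacing))
  }, numeric(3)))
  structure(list(target_spacing = as.numeric(target_spacing),
                 hu_lo = q[1], hu_hi = q[2],
                 median_size = apply(sizes, 2, stats::median)),
            class = "DatasetFingerprint")
}

#' @rdname computeFingerprint
#' @param fingerprint a `DatasetFingerprint`.
#' @param path JSON file path.
#' @export
writeFingerprint <- function(fingerprint, path) {
  jsonlite::write_json(unclass(fingerprint), path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname computeFingerprint
#' @export
readFingerprint <- function(path) {
  fp <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(fp, class = "DatasetFingerprint")
}

#' Resample a volume to a target spacing
#'
#' The new grid preserves physical extent: the size along each axis becomes
#' `round(old_size * old_spacing / target_spacing)` (at least 1).  Images use
#' trilinear interpolation; label volumes and masks use nearest-neighbour so
#' no new label values are invented.
#'
#' @param volume a [Volume-class].
#' @param target_spacing numeric(3) target spacing, mm, (z, y, x).
#' @param mode `"auto"` (continuous for images/probabilities, nearest for
#'   labels/masks), `"continuous"` or `"nearest"`.
#' @return a volume of the same class on the new grid.
#' @export
resampleVolume <- function(volume, target_spacing,
                           mode = c("auto", "continuous", "nearest")) {
  mode <- match.arg(mode)
  stopifnot(is(volume, "Volume"))
  if (any(target_spacing <= 0)) stop("target spacing must be positive")
  g <- volume@geometry
  if (mode == "auto")
    mode <- if (is(volume, "LabelVolume") || is(volume, "BinaryMask"))
      "nearest" else "continuous"
  new_size <- pmax(1L, as.integer(round(g@size * g@spacing / target_spacing)))
  if (identical(new_size, g@size) &&
      isTRUE(all.equal(as.numeric(target_spacing), g@spacing))) {
    return(volume)
  }
  vals <- .resample3d(as.numeric(volume@values), g@size, g@spacing,
                      new_size, as.numeric(target_spacing),
                      nearest = (mode == "nearest"))
  out_geom <- VolumeGeometry(new_size, target_spacing, g@origin)
  cls <- class(volume)
  if (cls %in% c("LabelVolume", "BinaryMask")) storage.mode(vals) <- "integer"
  new(cls, values = vals, geometry = out_geom)
}

#' Clip Hounsfield values to fingerprint bounds
#'
#' Saturates every voxel into `[hu_lo, hu_hi]`; in-range voxels are unchanged.
#'
#' @param image an [ImageVolume-class].
#' @param hu_lo,hu_hi clip bounds, `hu_lo < hu_hi`.
#' @return clipped [ImageVolume-class].
#' @export
clipHu <- function(image, hu_lo, hu_hi) {
  stopifnot(is(image, "ImageVolume"))
  if (hu_lo >= hu_hi) stop("hu_lo must be < hu_hi")
  v <- pmin(pmax(voxelData(image), hu_lo), hu_hi)
  new("ImageVolume", values = array(v, dim = dim(image)), geometry = image@geometry)
}

#' Z-score normalize an image volume
#'
#' Subtracts the per-sample mean and divides by the per-sample standard
#' deviation, so the output has mean 0 and SD 1.  Statistics are computed over
#' the whole sample.  A near-constant volume (SD below 1e-8) is rejected.
#'
#' @param image an [ImageVolume-class].
#' @return list with `image` (normalized [ImageVolume-class]) and `stats`
#'   (list with `mean` and `std`).
#' @export
znormalize <- function(image) {
  stopifnot(is(image, "ImageVolume"))
  v <- voxelData(image)
  m <- mean(v)
  s <- sd(as.vector(v))
  if (!is.finite(s) || s < 1e-8)
    stop("constant volume: standard deviation below 1e-8, cannot z-score")
  out <- (v - m) / s
  list(image = new("ImageVolume", values = array(out, dim = dim(v)),
                   geometry = image@geometry),
       stats = list(mean = m, std = s))
}

#' Apply the full preprocessing chain to one sample
#'
#' Resample (image: trilinear, labels: nearest) to the fingerprint's target
#' spacing, clip HU to the fingerprint bounds, z-score.  Returns the
#' normalized image, the resampled label volume, the merged binary foreground
#' mask and the normalization statistics.
#'
#' @param sample a [PhantomSample-class] or list with `$image`, `$labels`.
#' @param fingerprint a [computeFingerprint()] result.
#' @return list with `image`, `labels`, `mask`, `stats`.
#' @export
preprocessSample <- function(sample, fingerprint) {
  stopifnot(inherits(fingerprint, "DatasetFingerprint"))
  img <- resampleVolume(.sampleImage(sample), fingerprint$target_spacing)
  lab <- resampleVolume(.sampleLabels(sample), fingerprint$target_spacing)
  img <- clipHu(img, fingerprint$hu_lo, fingerprint$hu_hi)
  zn <- znormalize(img)
  list(image = zn$image, labels = lab, mask = mergeLabels(lab),
       stats = zn$stats)
}
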