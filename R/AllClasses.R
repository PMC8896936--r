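#' Volume geometry
#'
#' Physical geometry of a voxel grid: grid size, per-axis voxel spacing and
#' the physical position of the first voxel.  All per-axis quantities use the
#' package-wide axis order (z, y, x) — slice-stack first, matching the usual
#' CT convention of quoting a volume as slices x rows x columns.
#'
#' @slot size integer(3), voxels per axis (z, y, x).
#' @slot spacing numeric(3), voxel spacing in mm per axis (z, y, x).
#' @slot origin numeric(3), physical mm position of voxel (1,1,1).
#' @export
setClass("VolumeGeometry",
  representation(size = "integer", spacing = "numeric", origin = "numeric"),
  validity = function(object) {
    if (length(object@size) != 3L || any(object@size < 1L))
      return("size must be 3 integers >= 1")
    if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
        any(object@spacing <= 0))
      return("spacing must be 3 positive numbers (mm)")
    if (length(object@origin) != 3L || any(!is.finite(object@origin)))
      return("origin must be 3 finite numbers (mm)")
    TRUE
  })

#' @describeIn VolumeGeometry-class constructor.
#' @param size,spacing,origin see slots.
#' @export
VolumeGeometry <- function(size, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  new("VolumeGeometry", size = as.integer(size), spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' Voxel volumes
#'
#' `Volume` is the virtual parent of the four voxel-grid containers used
#' throughout the package; all carry a 3D array in (z, y, x) axis order plus a
#' [VolumeGeometry-class].  `ImageVolume` holds scalar intensities
#' (Hounsfield units before normalisation), `LabelVolume` holds instance-style
#' integer labels restricted to \{-1, 0, 1, 2, 3, 4\} (-1 marks a fracture of
#' uncertain type), `BinaryMask` holds \{0, 1\} and `ProbabilityVolume` holds
#' per-voxel foreground probabilities in [0, 1].
#'
#' @slot values 3D array, shape equal to the geometry's size.
#' @slot geometry a [VolumeGeometry-class].
#' @aliases ImageVolume-class LabelVolume-class BinaryMask-class
#'   ProbabilityVolume-class
#' @export
setClass("Volume", representation("VIRTUAL",
  values = "array", geometry = "VolumeGeometry"),
  validity = function(object) {
    d <- dim(object@values)
    if (length(d) != 3L) return("values must be a 3D array")
    if (!identical(as.integer(d), object@geometry@size))
      return("array shape does not match geometry size")
    TRUE
  })

#' @export
setClass("ImageVolume", contains = "Volume", validity = function(object) {
  if (!is.numeric(object@values)) return("image values must be numeric")
  TRUE
})

.LABEL_SET <- c(-1L, 0L, 1L, 2L, 3L, 4L)

#' @export
setClass("LabelVolume", contains = "Volume", validity = function(object) {
  v <- object@values
  if (!is.integer(v)) return("label values must be integer")
  bad <- setdiff(unique(as.vector(v)), .LABEL_SET)
  if (length(bad))
    return(sprintf("invalid label value(s): %s (allowed: -1, 0, 1..4)",
                   paste(bad, collapse = ", ")))
  TRUE
})

#' @export
setClass("BinaryMask", contains = "Volume", validity = function(object) {
  v <- object@values
  if (!all(v == 0L | v == 1L)) return("mask values must be 0 or 1")
  TRUE
})

#' @export
setClass("ProbabilityVolume", contains = "Volume", validity = function(object) {
  v <- object@values
  if (anyNA(v) || min(v) < 0 || max(v) > 1)
    return("probabilities must lie in [0, 1]")
  TRUE
})

.volume <- function(class, values, geometry = NULL, spacing = c(1, 1, 1),
                    origin = c(0, 0, 0)) {
  values <- as.array(values)
  if (is.null(geometry))
    geometry <- VolumeGeometry(dim(values), spacing, origin)
  new(class, values = values, geometry = geometry)
}

#' Construct voxel volumes
#'
#' Constructors for the four concrete [Volume-class] containers.  `values` is
#' a 3D array in (z, y, x) order; geometry may be given either as a
#' [VolumeGeometry-class] or via `spacing`/`origin`.
#'
#' @param values 3D array.
#' @param geometry optional [VolumeGeometry-class]; overrides
#'   `spacing`/`origin`.
#' @param spacing per-axis voxel spacing in mm, (z, y, x).
#' @param origin physical position of the first voxel in mm.
#' @return an object of the corresponding class.
#' @examples
#' img <- ImageVolume(array(rnorm(8), c(2, 2, 2)), spacing = c(1.25, 0.74, 0.74))
#' spacingMm(img)
#' @export
ImageVolume <- function(values, geometry = NULL, spacing = c(1, 1, 1),
                        origin = c(0, 0, 0)) {
  .volume("ImageVolume", values * 1.0, geometry, spacing, origin)
}

#' @rdname ImageVolume
#' @export
LabelVolume <- function(values, geometry = NULL, spacing = c(1, 1, 1),
                        origin = c(0, 0, 0)) {
  storage.mode(values) <- "integer"
  .volume("LabelVolume", values, geometry, spacing, origin)
}

#' @rdname ImageVolume
#' @export
BinaryMask <- function(values, geometry = NULL, spacing = c(1, 1, 1),
                       origin = c(0, 0, 0)) {
  storage.mode(values) <- "integer"
  .volume("BinaryMask", values, geometry, spacing, origin)
}

#' @rdname ImageVolume
#' @export
ProbabilityVolume <- function(values, geometry = NULL, spacing = c(1, 1, 1),
                              origin = c(0, 0, 0)) {
  .volume("ProbabilityVolume", values * 1.0, geometry, spacing, origin)
}

#' Phantom sample
#'
#' One synthetic CT-like volume: image (HU), instance-style labels, and the
#' catalogue of generated lesions and decoys.  `catalogue` has one row per
#' lesion: instance id, centroid voxel (z, y, x, 1-based), radius in mm and
#' the assigned class label; `decoys` lists off-rib confuser blobs that appear
#' in the image only (label stays 0).
#'
#' @slot image an [ImageVolume-class] in Hounsfield units.
#' @slot labels a [LabelVolume-class] sharing the image geometry.
#' @slot catalogue data.frame of lesions.
#' @slot decoys data.frame of decoy blobs.
#' @export
setClass("PhantomSample", representation(
  image = "ImageVolume", labels = "LabelVolume",
  catalogue = "data.frame", decoys = "data.frame"),
  validity = function(object) {
    gi <- object@image@geometry
    gl <- object@labels@geometry
    if (!identical(gi@size, gl@size) || !isTRUE(all.equal(gi@spacing, gl@spacing)))
      return("image and labels must share geometry")
    TRUE
  })

#' Candidate region set
#'
#' Connected components of a thresholded fused probability volume.  `labelmap`
#' assigns every voxel its component id (0 = background); `table` has one row
#' per retained candidate with its id, voxel count, bounding box, centroid and
#' mean probability, sorted by decreasing size.
#'
#' @slot labelmap integer 3D array of component ids.
#' @slot table data.frame of candidate summaries.
#' @slot geometry the [VolumeGeometry-class] of the source volume.
#' @slot threshold probability threshold used for binarisation.
#' @export
setClass("CandidateSet", representation(
  labelmap = "array", table = "data.frame", geometry = "VolumeGeometry",
  threshold = "numeric"))
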