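#' Read a volume from NIfTI
#'
#' Reads a NIfTI-1 file into the package's containers.  `kind = "label"`
#' validates that all values lie in the instance-label set \{-1, 0, 1..4\}
#' and errors otherwise; `kind = "mask"` validates \{0, 1\}.
#'
#' @param path a `.nii` / `.nii.gz` file.
#' @param kind `"image"`, `"label"` or `"mask"`.
#' @return an [ImageVolume-class], [LabelVolume-class] or [BinaryMask-class].
#' @seealso [writeVolume()], [mergeLabels()]
#' @export
readVolume <- function(path, kind = c("image", "label", "mask")) {
  kind <- match.arg(kind)
  nii <- readNifti(path)
  switch(kind,
    image = ImageVolume(nii$values, spacing = nii$spacing, origin = nii$origin),
    label = {
      v <- nii$values
      if (any(v != round(v))) stop("label volume has non-integer values: ", path)
      LabelVolume(v, spacing = nii$spacing, origin = nii$origin)
    },
    mask = BinaryMask(nii$values, spacing = nii$spacing, origin = nii$origin))
}

#' Write a volume to NIfTI
#'
#' Images and probability volumes are written as float32; label volumes as
#' signed 8-bit integers (so the uncertain-fracture label -1 round-trips
#' exactly); binary masks as unsigned 8-bit.
#'
#' @param volume a [Volume-class].
#' @param path output `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
writeVolume <- function(volume, path) {
  stopifnot(is(volume, "Volume"))
  g <- volume@geometry
  datatype <- if (is(volume, "LabelVolume")) "int8"
              else if (is(volume, "BinaryMask")) "uint8"
              else "float32"
  writeNifti(volume@values, path, spacing = g@spacing, origin = g@origin,
             datatype = datatype)
}

#' Merge instance-style fracture labels into one foreground class
#'
#' All fracture labels — the typed classes 1--4 and the uncertain class -1 —
#' are combined into a single binary foreground, so downstream segmentation is
#' binary fracture-vs-background.  A voxel is foreground iff its label is
#' non-zero; geometry is preserved.
#'
#' @param labels a [LabelVolume-class] (a [BinaryMask-class] is accepted and
#'   passed through, making the operation idempotent).
#' @return a [BinaryMask-class].
#' @examples
#' lab <- LabelVolume(array(c(0L, 3L, -1L, 0L, 1L, 4L, 0L, 2L), c(2, 2, 2)))
#' sum(voxelData(mergeLabels(lab)))  # 5 foreground voxels
#' @export
mergeLabels <- function(labels) {
  stopifnot(is(labels, "LabelVolume") || is(labels, "BinaryMask"))
  m <- array(as.integer(labels@values != 0L), dim = dim(labels@values))
  new("BinaryMask", values = m, geometry = labels@geometry)
}
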