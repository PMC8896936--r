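#' Accessors for voxel volumes
#'
#' `voxelData()` returns the raw 3D array, `geometry()` the
#' [VolumeGeometry-class], `spacingMm()`/`originMm()`/`gridSize()` its
#' components.
#'
#' @param x a [Volume-class], [PhantomSample-class] or [CandidateSet-class].
#' @return the requested component.
#' @name volume-accessors
NULL

#' @rdname volume-accessors
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))

#' @rdname volume-accessors
#' @export
setGeneric("geometry", function(x) standardGeneric("geometry"))

#' @rdname volume-accessors
#' @export
setGeneric("spacingMm", function(x) standardGeneric("spacingMm"))

#' @rdname volume-accessors
#' @export
setGeneric("originMm", function(x) standardGeneric("originMm"))

#' @rdname volume-accessors
#' @export
setGeneric("gridSize", function(x) standardGeneric("gridSize"))

#' @rdname volume-accessors
#' @export
setMethod("voxelData", "Volume", function(x) x@values)

#' @rdname volume-accessors
#' @export
setMethod("geometry", "Volume", function(x) x@geometry)

#' @rdname volume-accessors
#' @export
setMethod("geometry", "CandidateSet", function(x) x@geometry)

#' @rdname volume-accessors
#' @export
setMethod("spacingMm", "VolumeGeometry", function(x) x@spacing)

#' @rdname volume-accessors
#' @export
setMethod("spacingMm", "Volume", function(x) x@geometry@spacing)

#' @rdname volume-accessors
#' @export
setMethod("originMm", "VolumeGeometry", function(x) x@origin)

#' @rdname volume-accessors
#' @export
setMethod("originMm", "Volume", function(x) x@geometry@origin)

#' @rdname volume-accessors
#' @export
setMethod("gridSize", "VolumeGeometry", function(x) x@size)

#' @rdname volume-accessors
#' @export
setMethod("gridSize", "Volume", function(x) x@geometry@size)

#' @rdname volume-accessors
#' @export
setMethod("dim", "Volume", function(x) dim(x@values))

#' Phantom sample accessors
#'
#' @param x a [PhantomSample-class].
#' @return the image, label volume, lesion catalogue or decoy table.
#' @name phantom-accessors
NULL

#' @rdname phantom-accessors
#' @export
setGeneric("phantomImage", function(x) standardGeneric("phantomImage"))

#' @rdname phantom-accessors
#' @export
setGeneric("phantomLabels", function(x) standardGeneric("phantomLabels"))

#' @rdname phantom-accessors
#' @export
setGeneric("lesionCatalogue", function(x) standardGeneric("lesionCatalogue"))

#' @rdname phantom-accessors
#' @export
setGeneric("decoyCatalogue", function(x) standardGeneric("decoyCatalogue"))

#' @rdname phantom-accessors
#' @export
setMethod("phantomImage", "PhantomSample", function(x) x@image)

#' @rdname phantom-accessors
#' @export
setMethod("phantomLabels", "PhantomSample", function(x) x@labels)

#' @rdname phantom-accessors
#' @export
setMethod("lesionCatalogue", "PhantomSample", function(x) x@catalogue)

#' @rdname phantom-accessors
#' @export
setMethod("decoyCatalogue", "PhantomSample", function(x) x@decoys)

#' Candidate set accessors
#'
#' @param x a [CandidateSet-class].
#' @return `candidateTable()` the per-candidate summary data.frame;
#'   `componentMap()` the integer component-id volume.
#' @name candidate-accessors
NULL

#' @rdname candidate-accessors
#' @export
setGeneric("candidateTable", function(x) standardGeneric("candidateTable"))

#' @rdname candidate-accessors
#' @export
setGeneric("componentMap", function(x) standardGeneric("componentMap"))

#' @rdname candidate-accessors
#' @export
setMethod("candidateTable", "CandidateSet", function(x) x@table)

#' @rdname candidate-accessors
#' @export
setMethod("componentMap", "CandidateSet", function(x) x@labelmap)

setMethod("show", "VolumeGeometry", function(object) {
  cat(sprintf("VolumeGeometry: %s voxels (z,y,x), spacing %s mm, origin %s mm\n",
              paste(object@size, collapse = "x"),
              paste(signif(object@spacing, 4), collapse = "x"),
              paste(signif(object@origin, 4), collapse = ", ")))
})

setMethod("show", "Volume", function(object) {
  v <- object@values
  cat(sprintf("%s: %s voxels (z,y,x), spacing %s mm, range [%s, %s]\n",
              class(object),
              paste(dim(v), collapse = "x"),
              paste(signif(object@geometry@spacing, 4), collapse = "x"),
              signif(min(v), 5), signif(max(v), 5)))
})

setMethod("show", "PhantomSample", function(object) {
  cat(sprintf("PhantomSample: %s voxels, %d lesion(s), %d decoy(s)\n",
              paste(dim(object@image@values), collapse = "x"),
              nrow(object@catalogue), nrow(object@decoys)))
})

setMethod("show", "CandidateSet", function(object) {
  cat(sprintf("CandidateSet: %d candidate(s) at threshold %.3g\n",
              nrow(object@table), object@threshold))
  if (nrow(object@table)) print(head(object@table, 5))
})
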