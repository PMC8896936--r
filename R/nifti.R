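# Minimal NIfTI-1 reader/writer (.nii / .nii.gz), sufficient for this
# package's axis-aligned CT-like volumes.  Only scaling + translation affines
# are supported; anything oblique is rejected.  On-disk voxel order is the
# NIfTI-standard x-fastest; in memory the package uses (z, y, x).

.NII_DTYPES <- list(
  uint8   = list(code = 2L,   size = 1L, what = "integer", signed = FALSE),
  int16   = list(code = 4L,   size = 2L, what = "integer", signed = TRUE),
  int32   = list(code = 8L,   size = 4L, what = "integer", signed = TRUE),
  float32 = list(code = 16L,  size = 4L, what = "double",  signed = TRUE),
  float64 = list(code = 64L,  size = 8L, what = "double",  signed = TRUE),
  int8    = list(code = 256L, size = 1L, what = "integer", signed = TRUE),
  uint16  = list(code = 512L, size = 2L, what = "integer", signed = FALSE)
)

.nii_con <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Write a raw voxel array as NIfTI-1
#'
#' Low-level writer used by [writeVolume()] and [writeSample()].  The array is
#' in (z, y, x) order with `spacing`/`origin` quoted the same way; the file is
#' written little-endian with an axis-aligned sform.
#'
#' @param values 3D array in (z, y, x) order.
#' @param path output path; a `.gz` suffix enables gzip compression.
#' @param spacing,origin per-axis geometry, (z, y, x), in mm.
#' @param datatype one of `"float32"`, `"float64"`, `"int8"`, `"int16"`,
#'   `"int32"`.
#' @return `path`, invisibly.
#' @export
writeNifti <- function(values, path, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                       datatype = "float32") {
  stopifnot(length(dim(values)) == 3L)
  dt <- .NII_DTYPES[[datatype]]
  if (is.null(dt)) stop("unsupported datatype: ", datatype)
  d <- dim(values)                       # (D, H, W) = (z, y, x)
  con <- .nii_con(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  wc <- function(n) writeBin(raw(n), con)

  wi(348L, 4)                            # sizeof_hdr
  wc(10 + 18 + 4 + 2 + 1 + 1)            # data_type..dim_info
  wi(c(3L, d[3], d[2], d[1], 1L, 1L, 1L, 1L), 2)   # dim: x, y, z
  wf(c(0, 0, 0)); wi(0L, 2)              # intent_p*, intent_code
  wi(dt$code, 2); wi(dt$size * 8L, 2)    # datatype, bitpix
  wi(0L, 2)                              # slice_start
  wf(c(1, spacing[3], spacing[2], spacing[1], 0, 0, 0, 0))  # pixdim
  wf(352); wf(1); wf(0)                  # vox_offset, scl_slope, scl_inter
  wi(0L, 2); wc(1)                       # slice_end, slice_code
  writeBin(as.raw(2L), con)              # xyzt_units = mm
  wf(c(0, 0, 0, 0)); wi(c(0L, 0L), 4)    # cal_max..glmin
  wc(80 + 24)                            # descrip, aux_file
  wi(0L, 2); wi(1L, 2)                   # qform_code = 0, sform_code = 1
  wf(c(0, 0, 0)); wf(c(0, 0, 0))         # quatern, qoffset
  wf(c(spacing[3], 0, 0, origin[3]))     # srow_x
  wf(c(0, spacing[2], 0, origin[2]))     # srow_y
  wf(c(0, 0, spacing[1], origin[1]))     # srow_z
  wc(16)                                 # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)  # magic
  wc(4)                                  # extension flag

  disk <- aperm(values, c(3, 2, 1))      # x fastest on disk
  if (dt$what == "integer") {
    writeBin(as.integer(disk), con, size = dt$size, endian = "little")
  } else {
    writeBin(as.numeric(disk), con, size = dt$size, endian = "little")
  }
  invisible(path)
}

#' Read a NIfTI-1 file
#'
#' Low-level reader returning the voxel array and geometry; used by
#' [readVolume()].  Handles both endiannesses and gzip compression; applies
#' any intensity scaling (`scl_slope`/`scl_inter`); rejects non-axis-aligned
#' affines.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return list with `values` (3D array, (z, y, x)), `spacing`, `origin`.
#' @export
readNifti <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- .nii_con(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 352L)
  if (length(hdr) < 348L) stop("not a NIfTI-1 file (truncated header): ", path)
  endian <- "little"
  geti <- function(off, size, n = 1L, signed = TRUE)
    readBin(hdr[(off + 1L):(off + size * n)], "integer", n = n, size = size,
            signed = signed, endian = endian)
  getf <- function(off, n = 1L)
    readBin(hdr[(off + 1L):(off + 4L * n)], "double", n = n, size = 4L,
            endian = endian)
  if (geti(0L, 4L) != 348L) {
    endian <- "big"
    if (geti(0L, 4L) != 348L) stop("not a NIfTI-1 file (bad sizeof_hdr): ", path)
  }
  dims <- geti(40L, 2L, n = 8L)
  if (dims[1] < 3L || any(dims[5:8] > 1L))
    stop("only 3D volumes are supported: ", path)
  nx <- dims[2]; ny <- dims[3]; nz <- max(dims[4], 1L)
  dtcode <- geti(70L, 2L)
  dt <- NULL
  for (nm in names(.NII_DTYPES))
    if (.NII_DTYPES[[nm]]$code == dtcode) dt <- .NII_DTYPES[[nm]]
  if (is.null(dt)) stop("unsupported NIfTI datatype code: ", dtcode)
  pixdim <- getf(76L, n = 8L)
  vox_offset <- getf(108L)
  scl_slope <- getf(112L); scl_inter <- getf(116L)
  sform_code <- geti(254L, 2L)
  spacing <- abs(pixdim[2:4])            # (x, y, z)
  origin <- c(0, 0, 0)
  if (sform_code > 0L) {
    srow <- rbind(getf(280L, 4L), getf(296L, 4L), getf(312L, 4L))
    m <- srow[, 1:3, drop = FALSE]
    offdiag <- m; diag(offdiag) <- 0
    if (any(abs(offdiag) > 1e-5 * max(abs(m), 1)))
      stop("non-axis-aligned affine not supported: ", path)
    spacing <- abs(diag(m))
    origin <- srow[, 4]
  }
  if (any(spacing <= 0)) stop("non-positive voxel spacing in header: ", path)

  nvox <- as.numeric(nx) * ny * nz
  skip <- vox_offset - 352L
  if (skip > 0) readBin(con, "raw", n = skip)
  data <- readBin(con, dt$what, n = nvox, size = dt$size,
                  signed = dt$signed, endian = endian)
  if (length(data) < nvox) stop("truncated NIfTI voxel data: ", path)
  if (scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    data <- data * scl_slope + scl_inter
  arr <- aperm(array(data, dim = c(nx, ny, nz)), c(3, 2, 1))
  list(values = arr,
       spacing = rev(spacing),           # to (z, y, x)
       origin = rev(origin))
}
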