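# Synthetic CT-like phantoms: curved bone-density tubes on a soft-tissue
# background, sphere-like lesions attached to the tubes (instance labels 1-4
# or -1 for "fracture of uncertain type"), optional off-rib decoy blobs at
# lesion intensity, plus additive Gaussian noise.  Everything is a pure
# function of (config, index).

#' Phantom generator configuration
#'
#' Defines the stated world the phantoms are drawn from.  Defaults emulate a
#' desk-scale thoracic CT excerpt: a 64^3 grid with anisotropic spacing
#' (slices thicker than the in-plane pixels), rib-like tubes at bone density
#' (+700 HU) on a soft-tissue background (-50 HU), lesions at +200 HU
#' (between soft tissue and bone, as fresh fracture callus would be), 20 HU
#' additive noise, and 20% of lesions labelled -1 (uncertain type).  Decoy
#' blobs share the lesion intensity but are placed away from any rib, so only
#' spatial context distinguishes them from true lesions.
#'
#' @param grid_size integer(3), voxels per axis (z, y, x); each >= 16.
#' @param spacing_mm numeric(3), voxel spacing in mm (z, y, x).
#' @param n_ribs number of tubular structures.
#' @param n_lesions number of lesions attached to ribs.
#' @param lesion_radius_mm length-2 (min, max) lesion radius in mm.
#' @param hu_background,hu_bone,hu_lesion Hounsfield levels.
#' @param noise_sd additive Gaussian noise SD in HU.
#' @param uncertain_fraction probability a lesion gets label -1 instead of a
#'   type in 1..4.
#' @param n_decoys number of off-rib decoy blobs (image only, label 0).
#' @param decoy_hu Hounsfield level of decoys (default: the lesion level).
#' @param seed RNG seed; together with the sample index it fully determines a
#'   phantom.
#' @return a validated list of class `PhantomConfig`.
#' @examples
#' cfg <- phantomConfig(grid_size = c(32, 32, 32), n_lesions = 2)
#' sample <- generatePhantom(cfg, index = 0)
#' lesionCatalogue(sample)
#' @export
phantomConfig <- function(grid_size = c(64, 64, 64),
                          spacing_mm = c(1.25, 0.74, 0.74),
                          n_ribs = 3, n_lesions = 3,
                          lesion_radius_mm = c(2, 4),
                          hu_background = -50, hu_bone = 700, hu_lesion = 200,
                          noise_sd = 20, uncertain_fraction = 0.2,
                          n_decoys = 0, decoy_hu = hu_lesion,
                          seed = 42) {
  grid_size <- as.integer(grid_size)
  if (length(grid_size) != 3L || any(grid_size < 16L))
    stop("grid_size must be 3 integers >= 16")
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0))
    stop("spacing_mm must be 3 positive numbers")
  if (uncertain_fraction < 0 || uncertain_fraction > 1)
    stop("uncertain_fraction must lie in [0, 1]")
  if (length(lesion_radius_mm) != 2L || lesion_radius_mm[1] > lesion_radius_mm[2] ||
      lesion_radius_mm[1] <= 0)
    stop("lesion_radius_mm must be (min, max) with 0 < min <= max")
  if (n_ribs < 1) stop("n_ribs must be >= 1")
  if (n_lesions < 0 || n_decoys < 0) stop("counts must be non-negative")
  structure(list(
    grid_size = grid_size, spacing_mm = as.numeric(spacing_mm),
    n_ribs = as.integer(n_ribs), n_lesions = as.integer(n_lesions),
    lesion_radius_mm = as.numeric(lesion_radius_mm),
    hu_background = hu_background, hu_bone = hu_bone, hu_lesion = hu_lesion,
    noise_sd = noise_sd, uncertain_fraction = uncertain_fraction,
    n_decoys = as.integer(n_decoys), decoy_hu = decoy_hu,
    seed = as.integer(seed)), class = "PhantomConfig")
}

# Linear indices of voxels inside a sphere of radius r_mm around a physical
# point (given in voxel coordinates, 1-based) on an anisotropic grid.
.sphereIndices <- function(center_vox, r_mm, spacing, dims) {
  lo <- pmax(1L, floor(center_vox - r_mm / spacing))
  hi <- pmin(dims, ceiling(center_vox + r_mm / spacing))
  if (any(lo > hi)) return(integer(0))
  zi <- lo[1]:hi[1]; yi <- lo[2]:hi[2]; xi <- lo[3]:hi[3]
  dz2 <- ((zi - center_vox[1]) * spacing[1])^2
  dy2 <- ((yi - center_vox[2]) * spacing[2])^2
  dx2 <- ((xi - center_vox[3]) * spacing[3])^2
  inside <- outer(outer(dz2, dy2, "+"), dx2, "+") <= r_mm^2
  if (!any(inside)) return(integer(0))
  grid <- as.matrix(expand.grid(z = zi, y = yi, x = xi))
  g <- grid[as.vector(inside), , drop = FALSE]
  g[, 1] + dims[1] * (g[, 2] - 1L) + dims[1] * dims[2] * (g[, 3] - 1L)
}

# Render one rib: an arc in the axial (y, x) plane with a slow sagittal (z)
# drift, stamped as overlapping spheres of the tube radius.
.renderRib <- function(dims, spacing, tube_r_mm) {
  extent <- dims * spacing
  cz <- runif(1, 0.2, 0.8) * extent[1]
  cy <- extent[2] / 2 + runif(1, -0.1, 0.1) * extent[2]
  cx <- extent[3] / 2 + runif(1, -0.1, 0.1) * extent[3]
  arc_r <- runif(1, 0.28, 0.4) * min(extent[2], extent[3])
  theta0 <- runif(1, 0, 2 * pi)
  span <- runif(1, 0.7, 1.2) * pi
  drift <- runif(1, -0.1, 0.1) * extent[1] / span
  step <- 0.5 * min(spacing)
  n_pts <- max(8L, ceiling(arc_r * span / step))
  theta <- theta0 + span * seq(0, 1, length.out = n_pts)
  pts_mm <- cbind(z = cz + drift * (theta - theta0),
                  y = cy + arc_r * sin(theta),
                  x = cx + arc_r * cos(theta))
  idx <- integer(0)
  for (i in seq_len(n_pts)) {
    cv <- pts_mm[i, ] / spacing + 1     # physical mm -> 1-based voxel coords
    if (any(cv < 1 - tube_r_mm / spacing) || any(cv > dims + tube_r_mm / spacing))
      next
    idx <- c(idx, .sphereIndices(cv, tube_r_mm, spacing, dims))
  }
  unique(idx)
}

#' Generate one seeded phantom
#'
#' Deterministic for a fixed `(config, index)` pair: the effective seed is
#' derived by hashing the config seed with the index, so datasets can be
#' regenerated sample by sample.  Ribs are rendered as curved tubes at
#' `hu_bone`; each lesion is a sphere centred on a rib voxel (guaranteeing
#' bone attachment) whose voxels are set to `hu_lesion` in the image and to
#' its class label in the label volume; decoys are identical spheres placed
#' away from every rib and left unlabelled; Gaussian noise is added to the
#' image only.  Lesions (and decoys) are kept at least one maximum lesion
#' diameter apart so the connected components of the label volume correspond
#' one-to-one to catalogue entries.
#'
#' @param config a [phantomConfig()].
#' @param index non-negative sample index.
#' @return a [PhantomSample-class].
#' @seealso [generateDataset()], [writeSample()]
#' @export
generatePhantom <- function(config, index = 0L) {
  stopifnot(inherits(config, "PhantomConfig"), index >= 0)
  dims <- config$grid_size
  sp <- config$spacing_mm
  withSeed(deriveSeed(config$seed, "phantom", index), {
    n <- prod(dims)
    image <- array(config$hu_background, dim = dims)
    labels <- array(0L, dim = dims)
    tube_r <- max(1.8, 1.1 * max(sp))
    rib_idx <- integer(0)
    for (r in seq_len(config$n_ribs))
      rib_idx <- c(rib_idx, .renderRib(dims, sp, tube_r))
    rib_idx <- unique(rib_idx)
    if (!length(rib_idx))
      stop("phantom rib rendering produced no bone voxels (grid too small?)")
    image[rib_idx] <- config$hu_bone
    rib_coord <- arrayInd(rib_idx, dims)          # n x 3, (z, y, x)
    rib_mm <- sweep(rib_coord - 1, 2, sp, "*")

    min_sep <- 2 * config$lesion_radius_mm[2] + max(sp)
    centers_mm <- matrix(numeric(0), ncol = 3)
    catalogue <- data.frame(instance = integer(0), z = integer(0),
                            y = integer(0), x = integer(0),
                            radius_mm = numeric(0), label = integer(0))
    placeError <- function(what, j) {
      stop(structure(class = c("fk_placement_error", "error", "condition"),
        list(message = sprintf(
          "could not place %s %d after 100 retries (grid too small or crowded)",
          what, j), call = sys.call(-1))))
    }
    for (j in seq_len(config$n_lesions)) {
      placed <- FALSE
      for (try in 1:100) {
        k <- sample.int(nrow(rib_coord), 1L)
        cen_vox <- rib_coord[k, ]
        cen_mm <- (cen_vox - 1) * sp
        if (nrow(centers_mm) &&
            min(sqrt(rowSums(sweep(centers_mm, 2, cen_mm)^2))) < min_sep)
          next
        r_mm <- runif(1, config$lesion_radius_mm[1], config$lesion_radius_mm[2])
        idx <- .sphereIndices(cen_vox, r_mm, sp, dims)
        if (!length(idx)) next
        lab <- if (runif(1) < config$uncertain_fraction) -1L
               else sample.int(4L, 1L)
        image[idx] <- config$hu_lesion
        labels[idx] <- lab
        centers_mm <- rbind(centers_mm, cen_mm)
        catalogue <- rbind(catalogue, data.frame(
          instance = j, z = cen_vox[1], y = cen_vox[2], x = cen_vox[3],
          radius_mm = r_mm, label = lab))
        placed <- TRUE
        break
      }
      if (!placed) placeError("lesion", j)
    }

    decoys <- data.frame(z = integer(0), y = integer(0), x = integer(0),
                         radius_mm = numeric(0))
    clearance <- config$lesion_radius_mm[2] + 2 * max(sp) + 2  # mm off-rib
    for (j in seq_len(config$n_decoys)) {
      placed <- FALSE
      for (try in 1:100) {
        cen_vox <- sapply(dims, function(d) sample.int(d, 1L))
        cen_mm <- (cen_vox - 1) * sp
        if (min(sqrt(rowSums(sweep(rib_mm, 2, cen_mm)^2))) < clearance) next
        if (nrow(centers_mm) &&
            min(sqrt(rowSums(sweep(centers_mm, 2, cen_mm)^2))) < min_sep)
          next
        r_mm <- runif(1, config$lesion_radius_mm[1], config$lesion_radius_mm[2])
        idx <- .sphereIndices(cen_vox, r_mm, sp, dims)
        if (!length(idx)) next
        image[idx] <- config$decoy_hu
        centers_mm <- rbind(centers_mm, cen_mm)
        decoys <- rbind(decoys, data.frame(
          z = cen_vox[1], y = cen_vox[2], x = cen_vox[3], radius_mm = r_mm))
        placed <- TRUE
        break
      }
      if (!placed) placeError("decoy", j)
    }

    if (config$noise_sd > 0)
      image <- image + array(rnorm(n, 0, config$noise_sd), dim = dims)

    new("PhantomSample",
        image = ImageVolume(image, spacing = sp),
        labels = LabelVolume(labels, spacing = sp),
        catalogue = catalogue, decoys = decoys)
  })
}

#' Generate a phantom dataset
#'
#' Samples are indexed `0..n-1`; each is independently reproducible via
#' `generatePhantom(config, i)`.
#'
#' @param config a [phantomConfig()].
#' @param n number of samples, >= 1.
#' @return list of [PhantomSample-class] objects.
#' @export
generateDataset <- function(config, n) {
  if (!is.numeric(n) || n < 1) stop("n must be >= 1")
  lapply(seq_len(n) - 1L, function(i) {
    tryCatch(generatePhantom(config, i), fk_placement_error = function(e) {
      stop(sprintf("sample index %d: %s", i, conditionMessage(e)), call. = FALSE)
    })
  })
}

#' Write a phantom sample to disk
#'
#' Writes the image and label volumes as NIfTI (label volume as signed 8-bit,
#' preserving -1 exactly) and, optionally, a JSON sidecar with the lesion
#' catalogue and decoy table.
#'
#' @param sample a [PhantomSample-class].
#' @param image_path,label_path output NIfTI paths.
#' @param catalogue_path optional JSON sidecar path.
#' @return invisibly, the paths written.
#' @export
writeSample <- function(sample, image_path, label_path, catalogue_path = NULL) {
  stopifnot(is(sample, "PhantomSample"))
  writeVolume(sample@image, image_path)
  writeVolume(sample@labels, label_path)
  if (!is.null(catalogue_path))
    jsonlite::write_json(list(catalogue = sample@catalogue,
                              decoys = sample@decoys),
                         catalogue_path, digits = NA)
  invisible(c(image_path, label_path, catalogue_path))
}
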