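# Segmentation and detection metrics: voxel-overlap measures (Dice, IoU),
# surface-distance measures (ASSD, Hausdorff, with both the "0.95 x HD"
# convention and the common 95th-percentile variant), and instance-level
# detection rates.

.checkSameGeom <- function(a, b) {
  if (!identical(gridSize(a), gridSize(b)) ||
      !isTRUE(all.equal(spacingMm(a), spacingMm(b))))
    stop("masks have different geometry")
}

#' Voxel confusion counts
#'
#' True-positive, false-positive and false-negative voxel counts between a
#' predicted and a truth mask.
#'
#' @param pred,truth [BinaryMask-class]es on the same grid.
#' @return list with `tp`, `fp`, `fn`.
#' @export
confusion <- function(pred, truth) {
  stopifnot(is(pred, "BinaryMask"), is(truth, "BinaryMask"))
  .checkSameGeom(pred, truth)
  p <- voxelData(pred); t <- voxelData(truth)
  list(tp = sum(p == 1L & t == 1L),
       fp = sum(p == 1L & t == 0L),
       fn = sum(p == 0L & t == 1L))
}

#' Dice similarity coefficient
#'
#' `2 TP / (FP + 2 TP + FN)`; 1 for a perfect segmentation, 0 for disjoint
#' masks.  Two empty masks are defined as perfectly matching (Dice 1, with a
#' warning).
#'
#' @inheritParams confusion
#' @return value in `[0, 1]`.
#' @export
diceMetric <- function(pred, truth) {
  cm <- confusion(pred, truth)
  den <- cm$fp + 2 * cm$tp + cm$fn
  if (den == 0) {
    warning("both masks empty; Dice defined as 1")
    return(1)
  }
  2 * cm$tp / den
}

#' Intersection over union (Jaccard)
#'
#' `TP / (FP + TP + FN)`; related to Dice by `dice = 2 iou / (1 + iou)`.
#' Two empty masks give 1 with a warning.
#'
#' @inheritParams confusion
#' @return value in `[0, 1]`.
#' @export
iouMetric <- function(pred, truth) {
  cm <- confusion(pred, truth)
  den <- cm$fp + cm$tp + cm$fn
  if (den == 0) {
    warning("both masks empty; IoU defined as 1")
    return(1)
  }
  cm$tp / den
}

#' Surface voxels of a mask
#'
#' A foreground voxel belongs to the surface iff at least one of its six
#' face-neighbours is background, with the volume border counting as
#' background.  Coordinates are returned in physical mm (voxel index times
#' spacing).
#'
#' @param mask a [BinaryMask-class].
#' @return matrix with one surface point per row (columns z, y, x in mm);
#'   0 rows, with a warning, for an empty mask.
#' @export
surfaceVoxels <- function(mask) {
  stopifnot(is(mask, "BinaryMask"))
  m <- voxelData(mask)
  if (!any(m == 1L)) {
    warning("empty mask has no surface")
    return(matrix(numeric(0), ncol = 3, dimnames = list(NULL, c("z", "y", "x"))))
  }
  d <- dim(m)
  interior <- array(TRUE, dim = d)
  for (axis in 1:3) {
    n <- d[axis]
    if (n == 1L) { interior[] <- FALSE; break }
    lo <- vector("list", 3); hi <- vector("list", 3)
    for (a in 1:3) { lo[[a]] <- seq_len(d[a]); hi[[a]] <- seq_len(d[a]) }
    lo[[axis]] <- c(1L, seq_len(n - 1L))   # neighbour "below" (border clamps)
    hi[[axis]] <- c(seq_len(n - 1L) + 1L, n)
    below <- m[lo[[1]], lo[[2]], lo[[3]], drop = FALSE]
    above <- m[hi[[1]], hi[[2]], hi[[3]], drop = FALSE]
    # clamped self-comparison at borders: border voxels get neighbour = self,
    # fixed below by marking borders explicitly
    interior <- interior & below == 1L & above == 1L
    idx_border <- slice.index(m, axis)
    interior <- interior & idx_border != 1L & idx_border != n
  }
  surf <- which(m == 1L & !interior)
  co <- arrayInd(surf, d)
  sp <- spacingMm(mask)
  pts <- sweep((co - 1), 2, sp, "*")
  colnames(pts) <- c("z", "y", "x")
  pts
}

#' Average symmetric surface distance
#'
#' Mean of the nearest-surface distances taken in both directions between
#' the two masks' surface point sets, in mm.
#'
#' @inheritParams confusion
#' @return distance in mm.
#' @export
assd <- function(pred, truth) {
  .checkSameGeom(pred, truth)
  A <- surfaceVoxels(pred); B <- surfaceVoxels(truth)
  if (!nrow(A) || !nrow(B))
    stop("surface distance undefined for an empty mask")
  dab <- .min_dists(A, B)
  dba <- .min_dists(B, A)
  (sum(dab) + sum(dba)) / (nrow(A) + nrow(B))
}

#' Hausdorff distance and its 95% variants
#'
#' `hd` is the maximum over both directions of the nearest-surface distance.
#' `hd95_paper` is `0.95 * hd` (the scaled convention used when reporting a
#' "HD-95" that damps extreme outliers); `hd95_percentile` is the more common
#' 95th percentile of the pooled directed nearest-surface distances.  Both
#' variants are always returned.
#'
#' @inheritParams confusion
#' @return list with `hd`, `hd95_paper`, `hd95_percentile`, all mm.
#' @export
hausdorff <- function(pred, truth) {
  .checkSameGeom(pred, truth)
  A <- surfaceVoxels(pred); B <- surfaceVoxels(truth)
  if (!nrow(A) || !nrow(B))
    stop("surface distance undefined for an empty mask")
  dab <- .min_dists(A, B)
  dba <- .min_dists(B, A)
  hd <- max(max(dab), max(dba))
  list(hd = hd, hd95_paper = 0.95 * hd,
       hd95_percentile = unname(quantile(c(dab, dba), 0.95, type = 7)))
}

#' Full segmentation report
#'
#' @inheritParams confusion
#' @return list with `dice`, `iou`, `assd_mm`, `hd_mm`, `hd95_paper_mm`,
#'   `hd95_percentile_mm`.
#' @export
segmentationReport <- function(pred, truth) {
  d <- diceMetric(pred, truth)
  i <- iouMetric(pred, truth)
  empty <- sum(voxelData(pred)) == 0 || sum(voxelData(truth)) == 0
  both_empty <- sum(voxelData(pred)) == 0 && sum(voxelData(truth)) == 0
  if (both_empty) {
    h <- list(hd = 0, hd95_paper = 0, hd95_percentile = 0); a <- 0
  } else if (empty) {
    h <- list(hd = NA_real_, hd95_paper = NA_real_, hd95_percentile = NA_real_)
    a <- NA_real_
  } else {
    h <- hausdorff(pred, truth)
    a <- assd(pred, truth)
  }
  list(dice = d, iou = i, assd_mm = a, hd_mm = h$hd,
       hd95_paper_mm = h$hd95_paper, hd95_percentile_mm = h$hd95_percentile)
}

#' Instance-level detection report
#'
#' Truth instances are the connected components (26-connectivity) of the
#' merged truth mask.  A truth instance counts as detected iff at least one
#' accepted candidate shares a voxel with it; an accepted candidate with no
#' truth overlap counts as one false-positive prediction.  A candidate
#' overlapping several truth instances detects each of them but is a single
#' true-positive prediction.
#'
#' @param candidates a [CandidateSet-class].
#' @param truth_labels a [LabelVolume-class] (or [BinaryMask-class]) of truth
#'   instances on the same grid.
#' @param accepted_ids component ids accepted after stage 2 (default: all
#'   candidates in the table).
#' @return list with `n_truth_instances`, `n_detected`,
#'   `n_false_positive_predictions`, `n_predictions`, `recognition_rate`,
#'   `fp_rate`.
#' @export
detectionReport <- function(candidates, truth_labels, accepted_ids = NULL) {
  stopifnot(is(candidates, "CandidateSet"))
  if (!identical(gridSize(truth_labels), candidates@geometry@size))
    stop("candidates and truth have different geometry")
  truth_mask <- if (is(truth_labels, "LabelVolume")) mergeLabels(truth_labels)
                else truth_labels
  tm <- voxelData(truth_mask)
  d <- dim(tm)
  truth_comp <- .label_components(array(as.integer(tm), dim = d), d, 26L)
  n_truth <- max(truth_comp)
  ids <- accepted_ids %||% candidates@table$component_id
  lm <- candidates@labelmap
  detected <- logical(n_truth)
  n_fp <- 0L
  for (id in ids) {
    overlap <- unique(truth_comp[lm == id])
    overlap <- overlap[overlap > 0L]
    if (length(overlap)) detected[overlap] <- TRUE else n_fp <- n_fp + 1L
  }
  n_pred <- length(ids)
  list(n_truth_instances = n_truth,
       n_detected = sum(detected),
       n_false_positive_predictions = n_fp,
       n_predictions = n_pred,
       recognition_rate = if (n_truth > 0) sum(detected) / n_truth else NA_real_,
       fp_rate = if (n_pred > 0) n_fp / n_pred else 0)
}
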