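# Stage-1 training objective: L = L_dice + L_ce + w * L_contour.
# The contour term treats the predicted probability field as the smoothed
# indicator (Heaviside) of a level-set segmentation, so its integral of
# gradient magnitude is a contour-length penalty on the predicted boundary.

#' Loss configuration
#'
#' @param dice_smooth additive smoothing constant in the Dice ratio (> 0).
#'   Keeps the loss finite and differentiable on empty patches; default 1.
#' @param contour_weight multiplier on the contour-length term (>= 0).  The
#'   printed objective is the unweighted sum (weight 1); the knob exists
#'   because a length penalty can dominate on very small lesions.
#' @return list of class `LossConfig`.
#' @export
lossConfig <- function(dice_smooth = 1, contour_weight = 1) {
  if (dice_smooth <= 0) stop("dice_smooth must be > 0")
  if (contour_weight < 0) stop("contour_weight must be >= 0")
  structure(list(dice_smooth = dice_smooth, contour_weight = contour_weight),
            class = "LossConfig")
}

.lossArrays <- function(p, t) {
  pv <- if (is(p, "Volume")) voxelData(p) else p
  tv <- if (is(t, "Volume")) voxelData(t) else t
  if (!identical(dim(pv), dim(tv))) stop("prediction/target shape mismatch")
  list(p = pv, t = tv * 1.0)
}

#' Smoothed soft Dice loss
#'
#' `1 - (2 * sum(p * t) + s) / (sum(p) + sum(t) + s)` with smoothing `s`;
#' always in `[0, 1)`.
#'
#' @param p predicted probabilities ([ProbabilityVolume-class] or array).
#' @param t binary target ([BinaryMask-class] or array).
#' @param cfg a [lossConfig()].
#' @return scalar loss.
#' @export
diceLoss <- function(p, t, cfg = lossConfig()) {
  a <- .lossArrays(p, t)
  s <- cfg$dice_smooth
  1 - (2 * sum(a$p * a$t) + s) / (sum(a$p) + sum(a$t) + s)
}

.CE_EPS <- 1e-7

#' Binary cross-entropy loss
#'
#' Mean over voxels of `-[t log p + (1 - t) log(1 - p)]`, probabilities
#' clamped to `[1e-7, 1 - 1e-7]`.
#'
#' @inheritParams diceLoss
#' @return scalar loss, >= 0.
#' @export
crossEntropyLoss <- function(p, t) {
  a <- .lossArrays(p, t)
  pc <- pmin(pmax(a$p, .CE_EPS), 1 - .CE_EPS)
  -mean(a$t * log(pc) + (1 - a$t) * log(1 - pc))
}

# Central-difference gradient along one axis (one-sided at the borders);
# returns an array of the same shape.  `n >= 2` required.
.fdAxis <- function(a, axis) {
  perm <- c(axis, setdiff(1:3, axis))
  A <- aperm(a, perm)
  d <- dim(A)
  n <- d[1]
  M <- matrix(A, nrow = n)
  G <- matrix(0, nrow = n, ncol = ncol(M))
  if (n >= 3) G[2:(n - 1), ] <- (M[3:n, , drop = FALSE] - M[1:(n - 2), , drop = FALSE]) / 2
  G[1, ] <- M[2, ] - M[1, ]
  G[n, ] <- M[n, ] - M[n - 1, ]
  aperm(array(G, dim = d), order(perm))
}

# Adjoint (transpose) of .fdAxis, used in the loss gradient.
.fdAxisAdjoint <- function(u, axis) {
  perm <- c(axis, setdiff(1:3, axis))
  U <- aperm(u, perm)
  d <- dim(U)
  n <- d[1]
  M <- matrix(U, nrow = n)
  G <- matrix(0, nrow = n, ncol = ncol(M))
  if (n >= 3) {
    i <- 2:(n - 1)
    G[i + 1, ] <- G[i + 1, , drop = FALSE] + M[i, , drop = FALSE] / 2
    G[i - 1, ] <- G[i - 1, , drop = FALSE] - M[i, , drop = FALSE] / 2
  }
  G[2, ] <- G[2, ] + M[1, ]; G[1, ] <- G[1, ] - M[1, ]
  G[n, ] <- G[n, ] + M[n, ]; G[n - 1, ] <- G[n - 1, ] - M[n, ]
  aperm(array(G, dim = d), order(perm))
}

#' Contour-length (level-set) loss
#'
#' Discretizes the integral over the patch of the gradient magnitude of the
#' smoothed region indicator, identifying the predicted probability field
#' with that indicator: the mean over voxels of the Euclidean norm of the
#' central-finite-difference spatial gradient of `p` (voxel units).  Exactly 0
#' for any constant field; penalizes predicted boundary area.
#'
#' @param p predicted probabilities ([ProbabilityVolume-class] or 3D array)
#'   with every axis of length >= 2.
#' @param cfg a [lossConfig()] (unused by the bare term; kept for interface
#'   symmetry).
#' @return scalar loss, >= 0.
#' @export
contourLoss <- function(p, cfg = lossConfig()) {
  pv <- if (is(p, "Volume")) voxelData(p) else p
  if (any(dim(pv) < 2L)) stop("contour loss needs >= 2 voxels per axis")
  g2 <- .fdAxis(pv, 1)^2 + .fdAxis(pv, 2)^2 + .fdAxis(pv, 3)^2
  mean(sqrt(g2))
}

#' Composite segmentation loss
#'
#' `total = l_dice + l_ce + contour_weight * l_contour`, the three components
#' computed by [diceLoss()], [crossEntropyLoss()] and [contourLoss()].
#'
#' @inheritParams diceLoss
#' @return list of class `LossValues` with `l_dice`, `l_ce`, `l_contour`,
#'   `total`.
#' @export
totalLoss <- function(p, t, cfg = lossConfig()) {
  ld <- diceLoss(p, t, cfg)
  lc <- crossEntropyLoss(p, t)
  lk <- contourLoss(p, cfg)
  structure(list(l_dice = ld, l_ce = lc, l_contour = lk,
                 total = ld + lc + cfg$contour_weight * lk),
            class = "LossValues")
}

#' Gradient of the composite loss with respect to the probabilities
#'
#' Analytic `d total / d p`, used by the training loop (and verifiable by
#' finite differences wherever `p` is strictly inside `(0, 1)`).  The contour
#' term uses the exact adjoint of the finite-difference stencil, with the
#' subgradient 0 at voxels whose gradient magnitude vanishes.
#'
#' @inheritParams diceLoss
#' @return array of the same shape as `p`.
#' @export
totalLossGrad <- function(p, t, cfg = lossConfig()) {
  a <- .lossArrays(p, t)
  pv <- a$p; tv <- a$t
  n <- length(pv)
  s <- cfg$dice_smooth
  num <- 2 * sum(pv * tv) + s
  den <- sum(pv) + sum(tv) + s
  g_dice <- -(2 * tv * den - num) / den^2

  pc <- pmin(pmax(pv, .CE_EPS), 1 - .CE_EPS)
  inb <- (pv > .CE_EPS) & (pv < 1 - .CE_EPS)
  g_ce <- (-(tv / pc) + (1 - tv) / (1 - pc)) * inb / n

  gz <- .fdAxis(pv, 1); gy <- .fdAxis(pv, 2); gx <- .fdAxis(pv, 3)
  mag <- sqrt(gz^2 + gy^2 + gx^2)
  nz <- mag > 0
  uz <- array(0, dim(pv)); uy <- uz; ux <- uz
  uz[nz] <- gz[nz] / mag[nz]
  uy[nz] <- gy[nz] / mag[nz]
  ux[nz] <- gx[nz] / mag[nz]
  g_contour <- (.fdAxisAdjoint(uz, 1) + .fdAxisAdjoint(uy, 2) +
                .fdAxisAdjoint(ux, 3)) / n

  g_dice + g_ce + cfg$contour_weight * g_contour
}
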