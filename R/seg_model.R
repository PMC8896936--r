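# Stage-1 segmenter: a configurable 2D/3D encoder--decoder with skip
# connections, leaky-ReLU activations and instance normalisation, trained on
# sampled patches under the composite loss.  2D networks are handled as 3D
# networks with a singleton slice axis and in-plane kernels.

#' Segmenter configuration
#'
#' Describes an encoder--decoder segmentation network.  `pools_per_axis`
#' gives the number of 2x downsamplings per axis (axes may stop pooling
#' earlier than others, as with anisotropic CT); the network has
#' `max(pools_per_axis) + 1` resolution levels and `patch_size` must be
#' divisible by `2^pools_per_axis` on each axis.
#'
#' @param dims 2 or 3.
#' @param patch_size voxels per axis: 3 values `(z, y, x)` for 3D, 2 values
#'   `(y, x)` for 2D.
#' @param pools_per_axis downsampling count per axis (same length as
#'   `patch_size`).
#' @param base_channels channels at full resolution (doubled per level,
#'   capped at 320).
#' @param negative_slope leaky-ReLU slope.
#' @param in_channels input channels (2 for the cascade fine stage: image +
#'   coarse probability).
#' @return list of class `UNetConfig`.
#' @export
unetConfig <- function(dims = 3, patch_size = c(32, 32, 32),
                       pools_per_axis = c(2, 2, 2), base_channels = 4,
                       negative_slope = 0.01, in_channels = 1) {
  if (!dims %in% c(2, 3)) stop("dims must be 2 or 3")
  if (dims == 2) {
    if (length(patch_size) != 2L || length(pools_per_axis) != 2L)
      stop("2D config needs 2-vector patch_size and pools_per_axis")
    patch_size <- c(1L, patch_size)
    pools_per_axis <- c(0L, pools_per_axis)
  }
  patch_size <- as.integer(patch_size)
  pools_per_axis <- as.integer(pools_per_axis)
  if (length(patch_size) != 3L || length(pools_per_axis) != 3L)
    stop("patch_size/pools_per_axis must have 3 entries for 3D")
  if (any(patch_size %% 2L^pools_per_axis != 0L))
    stop("patch_size must be divisible by 2^pools_per_axis on each axis")
  structure(list(dims = dims, patch_size = patch_size,
                 pools_per_axis = pools_per_axis,
                 base_channels = as.integer(base_channels),
                 negative_slope = negative_slope,
                 in_channels = as.integer(in_channels)),
            class = "UNetConfig")
}

#' Named segmenter presets
#'
#' `paper_2d`, `paper_3d_lowres` and `paper_3d_fullres` reproduce the printed
#' full-scale configurations (2D 512x512 with [7,7] poolings; 3D 96x160x160
#' with [4,5,5] poolings); `tiny` is the desk-scale testing preset (32^3,
#' 2 poolings, 4 base channels).
#'
#' @param name preset name.
#' @param in_channels input channel count.
#' @return a [unetConfig()].
#' @export
unetPreset <- function(name = c("tiny", "paper_2d", "paper_3d_lowres",
                                "paper_3d_fullres"), in_channels = 1) {
  name <- match.arg(name)
  switch(name,
    tiny = unetConfig(3, c(32, 32, 32), c(2, 2, 2), 4,
                      in_channels = in_channels),
    paper_2d = unetConfig(2, c(512, 512), c(7, 7), 32,
                          in_channels = in_channels),
    paper_3d_lowres = unetConfig(3, c(96, 160, 160), c(4, 5, 5), 32,
                                 in_channels = in_channels),
    paper_3d_fullres = unetConfig(3, c(96, 160, 160), c(4, 5, 5), 32,
                                  in_channels = in_channels))
}

#' Training configuration
#'
#' @param batch_size patches per optimization step.
#' @param epochs training epochs.
#' @param learning_rate RMSprop learning rate.
#' @param fg_patch_fraction fraction of sampled patches forced to be centred
#'   on a foreground voxel (oversampling of the rare lesion class).
#' @param steps_per_epoch optimization steps per epoch (default: the number
#'   of training samples).
#' @param seed RNG seed for initialisation and patch sampling.
#' @return list of class `TrainConfig`.
#' @export
trainConfig <- function(batch_size = 2, epochs = 10, learning_rate = 1e-3,
                        fg_patch_fraction = 0.5, steps_per_epoch = NULL,
                        seed = 1) {
  if (batch_size < 1) stop("batch_size must be >= 1")
  if (fg_patch_fraction < 0 || fg_patch_fraction > 1)
    stop("fg_patch_fraction must lie in [0, 1]")
  if (epochs < 0) stop("epochs must be >= 0")
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 fg_patch_fraction = fg_patch_fraction,
                 steps_per_epoch = steps_per_epoch,
                 seed = as.integer(seed)), class = "TrainConfig")
}

.unetChannels <- function(cfg) {
  L <- max(cfg$pools_per_axis) + 1L
  pmin(cfg$base_channels * 2L^(seq_len(L) - 1L), 320L)
}

.unetFactors <- function(cfg) {
  L <- max(cfg$pools_per_axis) + 1L
  lapply(seq_len(L - 1L), function(l)
    ifelse(l <= cfg$pools_per_axis, 2L, 1L))
}

#' Build a segmentation operator
#'
#' Initializes a seeded encoder--decoder network per the configuration.  Use
#' [predictPatch()] to map an image patch to a probability patch of identical
#' spatial shape, or pass the model to [predictVolume()] for whole-volume
#' sliding-window inference.
#'
#' @param cfg a [unetConfig()].
#' @param seed integer seed for weight initialisation.
#' @return object of class `Segmenter`.
#' @export
buildSegmenter <- function(cfg, seed = 1) {
  stopifnot(inherits(cfg, "UNetConfig"))
  k <- if (cfg$dims == 2) c(1L, 3L, 3L) else c(3L, 3L, 3L)
  ch <- .unetChannels(cfg)
  L <- length(ch)
  params <- withSeed(seed, {
    enc <- lapply(seq_len(L), function(l) {
      ci <- if (l == 1L) cfg$in_channels else ch[l - 1L]
      list(block1 = .convBlockInit(ci, ch[l], k),
           block2 = .convBlockInit(ch[l], ch[l], k))
    })
    dec <- lapply(seq_len(L - 1L), function(l) {
      list(up = .convBlockInit(ch[l + 1L], ch[l], k),
           block1 = .convBlockInit(2L * ch[l], ch[l], k),
           block2 = .convBlockInit(ch[l], ch[l], k))
    })
    list(enc = enc, dec = dec,
         head = .convInit(ch[1L], 1L, c(1L, 1L, 1L)))
  })
  structure(list(cfg = cfg, params = params), class = "Segmenter")
}

.unetForward <- function(model, x, keep_cache = FALSE) {
  cfg <- model$cfg
  p <- model$params
  slope <- cfg$negative_slope
  factors <- .unetFactors(cfg)
  L <- length(p$enc)
  skips <- vector("list", L)
  enc_caches <- vector("list", L)
  pool_caches <- vector("list", L - 1L)
  for (l in seq_len(L)) {
    c1 <- .blockFwd(x, p$enc[[l]]$block1, slope)
    c2 <- .blockFwd(c1$y, p$enc[[l]]$block2, slope)
    skips[[l]] <- c2$y
    enc_caches[[l]] <- list(c1 = c1, c2 = c2)
    if (l < L) {
      if (all(factors[[l]] == 1L)) {
        pool_caches[[l]] <- NULL
        x <- c2$y
      } else {
        mp <- .maxpool3d_fwd(c2$y, dim(c2$y), factors[[l]])
        pool_caches[[l]] <- list(argmax = mp$argmax, in_dim = dim(c2$y))
        x <- mp$out
      }
    }
  }
  x <- skips[[L]]
  dec_caches <- vector("list", L - 1L)
  for (l in rev(seq_len(L - 1L))) {
    up_in_dim <- dim(x)
    x <- .upsample3d_fwd(x, dim(x), factors[[l]])
    up <- .blockFwd(x, p$dec[[l]]$up, slope)
    cat_in <- c(up$y, skips[[l]])
    dim(cat_in) <- c(dim(up$y)[1:3], dim(up$y)[4] + dim(skips[[l]])[4])
    b1 <- .blockFwd(cat_in, p$dec[[l]]$block1, slope)
    b2 <- .blockFwd(b1$y, p$dec[[l]]$block2, slope)
    dec_caches[[l]] <- list(up_in_dim = up_in_dim, up = up, b1 = b1, b2 = b2,
                            n_up = dim(up$y)[4])
    x <- b2$y
  }
  z <- .convFwd(x, p$head)
  prob <- .sigmoid(z)
  out <- list(prob = array(prob, dim = dim(prob)[1:3]))
  if (keep_cache)
    out$cache <- list(enc = enc_caches, pool = pool_caches, dec = dec_caches,
                      head_in = x, prob4 = prob, factors = factors)
  out
}

# Backward pass from dL/dprob; returns gradients with the params' shape.
.unetBackward <- function(model, cache, dprob) {
  cfg <- model$cfg
  p <- model$params
  slope <- cfg$negative_slope
  L <- length(p$enc)
  factors <- cache$factors
  dz <- array(as.numeric(dprob) * as.numeric(cache$prob4) *
                (1 - as.numeric(cache$prob4)), dim = dim(cache$prob4))
  hb <- .convBwd(cache$head_in, p$head, dz)
  g_head <- list(w = hb$gw, b = hb$gb)
  dx <- hb$dx
  g_dec <- vector("list", max(L - 1L, 0L))
  dskip <- vector("list", L)           # gradient flowing into each skip
  # decoder levels in forward-output order: dec[[1]] produced the head input,
  # dec[[l]] consumed the output of dec[[l+1]] (or of the bottom encoder)
  for (l in seq_len(L - 1L)) {
    dc <- cache$dec[[l]]
    b2 <- .blockBwd(dc$b2, p$dec[[l]]$block2, dx, slope)
    b1 <- .blockBwd(dc$b1, p$dec[[l]]$block1, b2$dx, slope)
    d_cat <- b1$dx
    n_up <- dc$n_up
    d_up_out <- d_cat[, , , seq_len(n_up), drop = FALSE]
    dskip[[l]] <- d_cat[, , , n_up + seq_len(dim(d_cat)[4] - n_up), drop = FALSE]
    up <- .blockBwd(dc$up, p$dec[[l]]$up, d_up_out, slope)
    g_dec[[l]] <- list(up = up$grads, block1 = b1$grads, block2 = b2$grads)
    dx <- .upsample3d_bwd(up$dx, dim(up$dx), factors[[l]])
  }
  # after the loop dx is the gradient at the bottom encoder level's output
  g_enc <- vector("list", L)
  for (l in rev(seq_len(L))) {
    d_out <- if (l == L) dx else dskip[[l]]
    ec <- cache$enc[[l]]
    b2 <- .blockBwd(ec$c2, p$enc[[l]]$block2, d_out, slope)
    b1 <- .blockBwd(ec$c1, p$enc[[l]]$block1, b2$dx, slope)
    g_enc[[l]] <- list(block1 = b1$grads, block2 = b2$grads)
    if (l > 1L) {
      # propagate through the pooling between level l-1 and l
      d_in <- b1$dx
      pc <- cache$pool[[l - 1L]]
      d_prev <- if (is.null(pc)) d_in
                else .maxpool3d_bwd(d_in, pc$argmax, pc$in_dim)
      dskip[[l - 1L]] <- .addGrads(dskip[[l - 1L]], d_prev)
    }
  }
  list(enc = g_enc, dec = g_dec, head = g_head)
}

#' Predict a single patch
#'
#' @param model a `Segmenter` from [buildSegmenter()] or [trainSegmenter()].
#' @param patch array of shape `patch_size` (a channel axis is added if
#'   absent; the cascade fine stage expects 2 channels).
#' @return 3D array of foreground probabilities, same spatial shape.
#' @export
predictPatch <- function(model, patch) {
  stopifnot(inherits(model, "Segmenter"))
  x <- .ensure4d(patch)
  if (dim(x)[4] != model$cfg$in_channels)
    stop(sprintf("patch has %d channel(s); model expects %d",
                 dim(x)[4], model$cfg$in_channels))
  if (!identical(as.integer(dim(x)[1:3]), model$cfg$patch_size))
    stop("patch spatial shape does not match model patch_size")
  .unetForward(model, x)$prob
}

# ---- patch sampling -------------------------------------------------------

# Crop `arr` (3D or 4D) at 1-based `origin` for `size` voxels, padding with
# `fill` where the window leaves the array.
.cropPad <- function(arr, origin, size, fill) {
  d3 <- dim(arr)[1:3]
  has_c <- length(dim(arr)) == 4L
  C <- if (has_c) dim(arr)[4] else 1L
  out <- array(fill, dim = c(size, C))
  lo <- pmax(origin, 1L)
  hi <- pmin(origin + size - 1L, d3)
  if (all(lo <= hi)) {
    src <- if (has_c) arr[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], , drop = FALSE]
           else arr[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    o <- lo - origin + 1L
    e <- o + (hi - lo)
    out[o[1]:e[1], o[2]:e[2], o[3]:e[3], ] <- src
  }
  if (!has_c) dim(out) <- size
  out
}

#' Sample a training patch
#'
#' With probability `fg_fraction` the patch is centred on a uniformly chosen
#' foreground voxel (foreground oversampling for the rare lesion class);
#' otherwise its origin is uniform over the valid range.  Volumes smaller
#' than the patch are padded: the image with its minimum value, the mask with
#' background.  Image and mask crops are co-located.  Draws from the current
#' RNG state.
#'
#' @param sample list with `image` ([ImageVolume-class]), `mask`
#'   ([BinaryMask-class]) and optionally `extra` (a [ProbabilityVolume-class]
#'   appended as a second channel, used by the cascade fine stage).
#' @param patch_size integer(3).
#' @param fg_fraction probability of forcing a foreground-centred patch.
#' @return list with `image` (array `(patch, channels)`) and `mask` (3D
#'   array).
#' @export
samplePatch <- function(sample, patch_size, fg_fraction = 0.5) {
  img <- voxelData(sample$image)
  msk <- voxelData(sample$mask)
  patch_size <- as.integer(patch_size)
  d <- dim(img)
  fg_idx <- which(msk == 1L)
  force_fg <- length(fg_idx) > 0L && runif(1) < fg_fraction
  max_origin <- pmax(d - patch_size + 1L, 1L)
  if (force_fg) {
    v <- arrayInd(fg_idx[sample.int(length(fg_idx), 1L)], d)[1, ]
    origin <- pmin(pmax(v - patch_size %/% 2L, 1L), max_origin)
  } else {
    origin <- vapply(max_origin, function(m) sample.int(m, 1L), integer(1))
  }
  fill <- min(img)
  ip <- .cropPad(img, origin, patch_size, fill)
  if (!is.null(sample$extra)) {
    ex <- voxelData(sample$extra)
    ep <- .cropPad(ex, origin, patch_size, 0)
    ip <- array(c(ip, ep), dim = c(patch_size, 2L))
  } else {
    dim(ip) <- c(patch_size, 1L)
  }
  mp <- .cropPad(msk, origin, patch_size, 0L)
  list(image = ip, mask = mp, origin = origin)
}

# ---- training -------------------------------------------------------------

#' Train the segmenter
#'
#' Mini-batch RMSprop on the composite loss over sampled patches.  Fully
#' reproducible for a fixed `train_cfg$seed`; the per-epoch mean of each loss
#' component is recorded.  Aborts on non-finite loss.
#'
#' @param dataset nonempty list of preprocessed samples (each a list with
#'   `image`, `mask`, optional `extra`; see [preprocessSample()]).
#' @param unet_cfg a [unetConfig()].
#' @param train_cfg a [trainConfig()].
#' @param loss_cfg a [lossConfig()].
#' @return list with `model` (`Segmenter`) and `history` (data.frame with one
#'   row per epoch: `epoch`, `l_dice`, `l_ce`, `l_contour`, `total`).
#' @export
trainSegmenter <- function(dataset, unet_cfg, train_cfg, loss_cfg = lossConfig()) {
  if (!length(dataset)) stop("empty dataset")
  stopifnot(inherits(unet_cfg, "UNetConfig"), inherits(train_cfg, "TrainConfig"))
  model <- buildSegmenter(unet_cfg, seed = deriveSeed(train_cfg$seed, "seg-init"))
  history <- data.frame(epoch = integer(0), l_dice = numeric(0),
                        l_ce = numeric(0), l_contour = numeric(0),
                        total = numeric(0))
  if (train_cfg$epochs == 0L) return(list(model = model, history = history))
  steps <- train_cfg$steps_per_epoch %||% length(dataset)
  state <- .rmspropInit(model$params)
  withSeed(deriveSeed(train_cfg$seed, "seg-train"), {
    for (epoch in seq_len(train_cfg$epochs)) {
      acc <- c(l_dice = 0, l_ce = 0, l_contour = 0, total = 0)
      nb <- 0L
      for (step in seq_len(steps)) {
        grads <- NULL
        for (b in seq_len(train_cfg$batch_size)) {
          si <- sample.int(length(dataset), 1L)
          pt <- samplePatch(dataset[[si]], unet_cfg$patch_size,
                            train_cfg$fg_patch_fraction)
          fw <- .unetForward(model, pt$image, keep_cache = TRUE)
          lv <- totalLoss(fw$prob, pt$mask, loss_cfg)
          if (!is.finite(lv$total))
            stop(sprintf("non-finite loss at epoch %d step %d (dice=%g ce=%g contour=%g)",
                         epoch, step, lv$l_dice, lv$l_ce, lv$l_contour))
          acc <- acc + unlist(lv)
          nb <- nb + 1L
          dprob <- totalLossGrad(fw$prob, pt$mask, loss_cfg)
          grads <- .addGrads(grads, .unetBackward(model, fw$cache, dprob))
        }
        grads <- .scaleGrads(grads, 1 / train_cfg$batch_size)
        upd <- .rmspropStep(model$params, grads, state, train_cfg$learning_rate)
        model$params <- upd$p
        state <- upd$s
      }
      history[nrow(history) + 1L, ] <- c(epoch, acc / nb)
    }
  })
  list(model = model, history = history)
}

#' Cascade configuration
#'
#' Coarse-to-fine segmentation: a coarse model trained at a lower resolution
#' (`coarse_spacing_mm`), whose upsampled probability is concatenated to the
#' full-resolution image as a second input channel of the fine model.
#'
#' @param coarse_spacing_mm numeric(3), coarse target spacing (each axis >=
#'   the fine spacing).
#' @param coarse,fine [unetConfig()]s; `fine$in_channels` must be 2.
#' @return list of class `CascadeConfig`.
#' @export
cascadeConfig <- function(coarse_spacing_mm, coarse, fine) {
  stopifnot(inherits(coarse, "UNetConfig"), inherits(fine, "UNetConfig"))
  if (fine$in_channels != 2L)
    stop("fine model must accept 2 input channels (image + coarse probability)")
  structure(list(coarse_spacing_mm = as.numeric(coarse_spacing_mm),
                 coarse = coarse, fine = fine), class = "CascadeConfig")
}

#' Train a coarse-to-fine cascade
#'
#' Trains the coarse model on volumes resampled to `coarse_spacing_mm`, runs
#' it over each training volume, upsamples its probability to the full grid
#' and trains the fine model with that probability as an extra input channel.
#'
#' @param dataset preprocessed samples as for [trainSegmenter()].
#' @param cascade_cfg a [cascadeConfig()].
#' @param train_cfg a [trainConfig()].
#' @param loss_cfg a [lossConfig()].
#' @param overlap sliding-window overlap used for the coarse pass.
#' @return list with `coarse`, `fine` (trained `Segmenter`s), their
#'   histories, and `coarse_spacing_mm`.
#' @export
trainCascade <- function(dataset, cascade_cfg, train_cfg,
                         loss_cfg = lossConfig(), overlap = 0.5) {
  stopifnot(inherits(cascade_cfg, "CascadeConfig"))
  cs <- cascade_cfg$coarse_spacing_mm
  coarse_data <- lapply(dataset, function(s) {
    list(image = resampleVolume(s$image, cs, "continuous"),
         mask = resampleVolume(s$mask, cs, "nearest"))
  })
  coarse <- trainSegmenter(coarse_data, cascade_cfg$coarse, train_cfg, loss_cfg)
  fine_data <- lapply(seq_along(dataset), function(i) {
    s <- dataset[[i]]
    cimg <- coarse_data[[i]]$image
    plan <- planWindows(geometry(cimg), cascade_cfg$coarse$patch_size, overlap)
    fused <- predictVolume(coarse$model, cimg, plan)
    pv <- ProbabilityVolume(pmin(pmax(fused$values, 0), 1),
                            geometry = geometry(cimg))
    up <- resampleVolume(pv, spacingMm(s$image), "continuous")
    uv <- voxelData(up)
    # extent rounding can differ by a voxel; crop/pad onto the fine grid
    uv <- .cropPad(uv, c(1L, 1L, 1L), dim(voxelData(s$image)), 0)
    s$extra <- ProbabilityVolume(pmin(pmax(uv, 0), 1),
                                 geometry = geometry(s$image))
    s
  })
  fine <- trainSegmenter(fine_data, cascade_cfg$fine, train_cfg, loss_cfg)
  list(coarse = coarse$model, fine = fine$model,
       coarse_history = coarse$history, fine_history = fine$history,
       coarse_spacing_mm = cs)
}
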