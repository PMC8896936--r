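# Stage-2 false-positive exclusion: one dense-connectivity 3D classifier per
# crop size, each mapping a cubic image crop to a fracture probability, fused
# by weights equal to each classifier's validation accuracy (normalized so
# the fusion stays a probability).

#' DenseNet classifier configuration
#'
#' Dense connectivity: within a block, each layer receives the concatenation
#' of the block input and all previous layer outputs, and contributes
#' `growth_rate` new channels; transition layers compress channels by
#' `compression` and halve resolution.  Defaults are desk-scale (two blocks
#' of two layers, growth 8); `paperLike = TRUE` deepens to three blocks of
#' four layers with growth 16.
#'
#' @param input_size cubic crop edge length (must match the crop fed in;
#'   divisible by `2^(number of blocks - 1)`).
#' @param growth_rate channels added per dense layer (>= 1).
#' @param block_layout integer vector, layers per dense block.
#' @param compression transition channel-reduction factor in (0, 1].
#' @param negative_slope leaky-ReLU slope.
#' @param paperLike deepen to a full-scale layout.
#' @return list of class `DenseNetConfig`.
#' @export
denseNetConfig <- function(input_size, growth_rate = 8,
                           block_layout = c(2, 2), compression = 0.5,
                           negative_slope = 0.01, paperLike = FALSE) {
  if (paperLike) {
    growth_rate <- 16; block_layout <- c(4, 4, 4)
  }
  input_size <- as.integer(input_size)
  if (growth_rate < 1) stop("growth_rate must be >= 1")
  if (compression <= 0 || compression > 1) stop("compression must be in (0, 1]")
  n_trans <- length(block_layout) - 1L
  if (input_size %% 2L^n_trans != 0L)
    stop("input_size must be divisible by 2^(number of transitions)")
  structure(list(input_size = input_size, growth_rate = as.integer(growth_rate),
                 block_layout = as.integer(block_layout),
                 compression = compression, negative_slope = negative_slope),
            class = "DenseNetConfig")
}

# pre-activation unit: instance norm -> leaky ReLU -> conv
# (IN parameters sized to the input channels, unlike the post-activation
# blocks of the segmenter)
.preBlockInit <- function(ci, co, k) {
  list(w = .heInit(k, ci, co), b = numeric(co),
       gamma = rep(1, ci), beta = numeric(ci))
}

.preBlockFwd <- function(x, p, slope) {
  innorm <- .inFwd(x, p$gamma, p$beta)
  pos <- (innorm$y > 0) * 1
  a <- .lrelu(innorm$y, pos, slope)
  dim(a) <- dim(x)
  y <- .convFwd(a, p)
  list(y = y, x = x, a = a, innorm = innorm, pos = pos)
}

.preBlockBwd <- function(cache, p, dy, slope) {
  cb <- .convBwd(cache$a, p, dy)
  da <- .lrelu(cb$dx, cache$pos, slope)
  dim(da) <- dim(cb$dx)
  ib <- .inBwd(da, cache$innorm, p$gamma, dim(cache$x))
  list(dx = ib$dx,
       grads = list(w = cb$gw, b = cb$gb, gamma = ib$dgamma, beta = ib$dbeta))
}

.denseChannels <- function(cfg, stem_channels) {
  ch <- stem_channels
  for (b in seq_along(cfg$block_layout)) {
    ch <- ch + cfg$block_layout[b] * cfg$growth_rate
    if (b < length(cfg$block_layout)) ch <- max(1L, floor(ch * cfg$compression))
  }
  ch
}

#' Build a crop classifier
#'
#' Initializes a seeded dense-connectivity 3D network mapping a cubic image
#' crop to a fracture probability: stem convolution, dense blocks with
#' pre-activation units, compressing/pooling transitions, then instance norm,
#' global average pooling and a single-logit sigmoid head.
#'
#' @param cfg a [denseNetConfig()].
#' @param seed weight-initialisation seed.
#' @return object of class `CropClassifier`.
#' @seealso [classifierProb()], [trainClassifierEnsemble()]
#' @export
buildClassifier <- function(cfg, seed = 1) {
  stopifnot(inherits(cfg, "DenseNetConfig"))
  k3 <- c(3L, 3L, 3L); k1 <- c(1L, 1L, 1L)
  g <- cfg$growth_rate
  stem_ch <- 2L * g
  params <- withSeed(seed, {
    stem <- .convInit(1L, stem_ch, k3)
    ch <- stem_ch
    blocks <- list(); trans <- list()
    for (b in seq_along(cfg$block_layout)) {
      layers <- list()
      for (j in seq_len(cfg$block_layout[b])) {
        layers[[j]] <- .preBlockInit(ch, g, k3)
        ch <- ch + g
      }
      blocks[[b]] <- layers
      if (b < length(cfg$block_layout)) {
        out_ch <- max(1L, floor(ch * cfg$compression))
        trans[[b]] <- .preBlockInit(ch, out_ch, k1)
        ch <- out_ch
      }
    }
    fc_in <- ch
    list(stem = stem, blocks = blocks, trans = trans,
         final_gamma = rep(1, fc_in), final_beta = numeric(fc_in),
         fc_w = rnorm(fc_in, sd = sqrt(1 / fc_in)), fc_b = 0)
  })
  structure(list(cfg = cfg, params = params), class = "CropClassifier")
}

.densenetForward <- function(model, x, keep_cache = FALSE) {
  cfg <- model$cfg
  p <- model$params
  slope <- cfg$negative_slope
  x <- .ensure4d(x)
  if (!identical(as.integer(dim(x)[1:3]), rep(cfg$input_size, 3L)))
    stop(sprintf("crop shape %s does not match classifier input size %d",
                 paste(dim(x)[1:3], collapse = "x"), cfg$input_size))
  stem <- .convFwd(x, p$stem)
  cur <- stem
  caches <- list(stem_in = x, blocks = list(), trans = list())
  for (b in seq_along(p$blocks)) {
    lay_caches <- list()
    for (j in seq_along(p$blocks[[b]])) {
      u <- .preBlockFwd(cur, p$blocks[[b]][[j]], slope)
      lay_caches[[j]] <- u
      nc <- dim(cur)[4] + dim(u$y)[4]
      cur <- array(c(cur, u$y), dim = c(dim(cur)[1:3], nc))
    }
    caches$blocks[[b]] <- lay_caches
    if (b < length(p$blocks)) {
      tr <- .preBlockFwd(cur, p$trans[[b]], slope)
      pooled <- .avgpoolFwd(tr$y, c(2L, 2L, 2L))
      caches$trans[[b]] <- list(unit = tr, pre_pool_dim = dim(tr$y))
      cur <- pooled
    }
  }
  fin <- .inFwd(cur, p$final_gamma, p$final_beta)
  pos <- fin$y > 0
  act <- ifelse(pos, fin$y, slope * fin$y)
  dim(act) <- dim(cur)
  C <- dim(cur)[4]
  feat <- colMeans(matrix(act, ncol = C))
  z <- as.numeric(sum(feat * as.numeric(p$fc_w)) + as.numeric(p$fc_b))
  prob <- .sigmoid(z)
  out <- list(prob = prob)
  if (keep_cache)
    out$cache <- c(caches, list(final_in = cur, fin = fin, pos = pos,
                                act_dim = dim(cur), feat = feat, z = z,
                                prob = prob))
  out
}

# Backward from dL/dz (gradient at the logit); returns grads shaped like params.
.densenetBackward <- function(model, cache, dz) {
  p <- model$params
  slope <- model$cfg$negative_slope
  d <- cache$act_dim
  C <- d[4]
  nvox <- prod(d[1:3])
  dz <- as.numeric(dz)
  g_fc_w <- cache$feat * dz
  g_fc_b <- dz
  dfeat <- as.numeric(p$fc_w) * dz
  dact <- matrix(rep(dfeat / nvox, each = nvox), ncol = C)
  dact <- dact * ifelse(matrix(cache$pos, ncol = C), 1, slope)
  ib <- .inBwd(array(dact, dim = d), cache$fin, p$final_gamma, d)
  g_final_gamma <- ib$dgamma
  g_final_beta <- ib$dbeta
  dcur <- ib$dx
  g_blocks <- vector("list", length(p$blocks))
  g_trans <- vector("list", length(p$trans))
  for (b in rev(seq_along(p$blocks))) {
    if (b < length(p$blocks)) {
      tc <- cache$trans[[b]]
      dpool <- .avgpoolBwd(dcur, c(2L, 2L, 2L))
      tb <- .preBlockBwd(tc$unit, p$trans[[b]], dpool, slope)
      g_trans[[b]] <- tb$grads
      dcur <- tb$dx
    }
    lay <- p$blocks[[b]]
    g_lay <- vector("list", length(lay))
    for (j in rev(seq_along(lay))) {
      u <- cache$blocks[[b]][[j]]
      cin <- dim(u$x)[4]
      dprev <- dcur[, , , seq_len(cin), drop = FALSE]
      dyj <- dcur[, , , cin + seq_len(dim(dcur)[4] - cin), drop = FALSE]
      ub <- .preBlockBwd(u, lay[[j]], dyj, slope)
      g_lay[[j]] <- ub$grads
      dcur <- dprev + ub$dx
    }
    g_blocks[[b]] <- g_lay
  }
  sb <- .convBwd(cache$stem_in, p$stem, dcur)
  list(stem = list(w = sb$gw, b = sb$gb), blocks = g_blocks, trans = g_trans,
       final_gamma = g_final_gamma, final_beta = g_final_beta,
       fc_w = g_fc_w, fc_b = g_fc_b)
}

#' Classify one crop
#'
#' @param model a `CropClassifier`.
#' @param crop cubic 3D array matching the configured input size.
#' @return fracture probability in `[0, 1]`.
#' @export
classifierProb <- function(model, crop) {
  stopifnot(inherits(model, "CropClassifier"))
  .densenetForward(model, crop)$prob
}

#' Label candidates against ground truth
#'
#' A candidate is a positive (label 1) iff its voxel set overlaps at least
#' one foreground voxel of the truth mask; otherwise 0.
#'
#' @param candidates a [CandidateSet-class].
#' @param truth a [BinaryMask-class] on the same grid.
#' @return the candidate table with an added `label` column.
#' @export
labelCandidates <- function(candidates, truth) {
  stopifnot(is(candidates, "CandidateSet"), is(truth, "BinaryMask"))
  if (!identical(gridSize(truth), candidates@geometry@size))
    stop("candidates and truth mask have different geometry")
  tab <- candidates@table
  tv <- voxelData(truth)
  lm <- candidates@labelmap
  tab$label <- vapply(tab$component_id, function(id)
    as.integer(any(tv[lm == id] == 1L)), integer(1))
  tab
}

.trainOneClassifier <- function(crops, labels, cfg, train_cfg,
                                balance_classes = TRUE) {
  model <- buildClassifier(cfg, seed = deriveSeed(train_cfg$seed, "cls-init",
                                                  cfg$input_size))
  state <- .rmspropInit(model$params)
  n <- length(crops)
  # balanced BCE: candidate mining yields many more negatives than positives,
  # and an unweighted loss then sacrifices positive recall
  n_pos <- sum(labels == 1L)
  w <- if (balance_classes && n_pos > 0L && n_pos < n) {
    ifelse(labels == 1L, n / (2 * n_pos), n / (2 * (n - n_pos)))
  } else rep(1, n)
  withSeed(deriveSeed(train_cfg$seed, "cls-train", cfg$input_size), {
    for (epoch in seq_len(train_cfg$epochs)) {
      ord <- sample.int(n)
      i <- 1L
      while (i <= n) {
        take <- ord[i:min(i + train_cfg$batch_size - 1L, n)]
        grads <- NULL
        for (t in take) {
          fw <- .densenetForward(model, crops[[t]], keep_cache = TRUE)
          dz <- (fw$prob - labels[t]) * w[t]   # weighted d(BCE)/d(logit)
          grads <- .addGrads(grads, .densenetBackward(model, fw$cache, dz))
        }
        grads <- .scaleGrads(grads, 1 / length(take))
        upd <- .rmspropStep(model$params, grads, state,
                            train_cfg$learning_rate)
        model$params <- upd$p
        state <- upd$s
        i <- i + train_cfg$batch_size
      }
    }
  })
  model
}

#' Train the three-size classifier ensemble
#'
#' Splits the labelled candidates into training and validation parts
#' (stratified by label, seeded, 25% validation), trains one classifier per
#' crop size on its own crops, and sets each fusion weight to that
#' classifier's validation accuracy at the 0.5 decision point.
#'
#' @param crops_per_candidate list over candidates of [cropMultiscale()]
#'   results (or plain lists of three crops, smallest first).
#' @param labels integer vector of candidate labels (1 fracture / 0 not).
#' @param configs list of three [denseNetConfig()]s, matching the crop sizes.
#' @param train_cfg a [trainConfig()].
#' @param val_fraction held-out fraction for the accuracy weights.
#' @param balance_classes weight the per-candidate cross-entropy inversely to
#'   class frequency (mined candidate sets are negative-heavy; an unweighted
#'   loss then trades away positive recall).  Default TRUE.
#' @return list of class `ClassifierEnsemble`: `models` (three
#'   `CropClassifier`s), `weights` (list with `lambda1..3`), `val_idx`.
#' @export
trainClassifierEnsemble <- function(crops_per_candidate, labels, configs,
                                    train_cfg, val_fraction = 0.25,
                                    balance_classes = TRUE) {
  n <- length(crops_per_candidate)
  stopifnot(n == length(labels), length(configs) == 3L)
  if (length(unique(labels)) < 2L)
    stop("degenerate labels: need at least one positive and one negative candidate")
  val_idx <- withSeed(deriveSeed(train_cfg$seed, "cls-split"), {
    pos <- which(labels == 1L); neg <- which(labels == 0L)
    c(if (length(pos) > 1L) sample(pos, max(1L, round(val_fraction * length(pos)))),
      if (length(neg) > 1L) sample(neg, max(1L, round(val_fraction * length(neg)))))
  })
  val_idx <- sort(unique(val_idx))
  train_idx <- setdiff(seq_len(n), val_idx)
  if (length(unique(labels[train_idx])) < 2L)
    stop("degenerate labels in the training split")
  getCrop <- function(cand, s) {
    if (inherits(cand, "MultiScaleCrops")) cand$crops[[s]] else cand[[s]]
  }
  models <- vector("list", 3L)
  lambdas <- numeric(3L)
  for (s in 1:3) {
    crops_s <- lapply(crops_per_candidate, getCrop, s = s)
    models[[s]] <- .trainOneClassifier(crops_s[train_idx], labels[train_idx],
                                       configs[[s]], train_cfg,
                                       balance_classes = balance_classes)
    if (length(val_idx)) {
      pred <- vapply(val_idx, function(i)
        classifierProb(models[[s]], crops_s[[i]]), numeric(1))
      lambdas[s] <- mean((pred >= 0.5) == (labels[val_idx] == 1L))
    } else {
      lambdas[s] <- 1
    }
  }
  structure(list(models = models,
                 weights = list(lambda1 = lambdas[1], lambda2 = lambdas[2],
                                lambda3 = lambdas[3]),
                 val_idx = val_idx),
            class = "ClassifierEnsemble")
}

#' Fuse per-size classification probabilities
#'
#' Weighted combination of the three crop-size probabilities with weights
#' equal to the per-size validation accuracies.  By default the weighted sum
#' is normalized by the weight total, making it a true weighted average
#' bounded by `[min(p), max(p)]`; `normalize = FALSE` gives the literal
#' unnormalized weighted sum (which can exceed 1).
#'
#' @param weights list with `lambda1`, `lambda2`, `lambda3`, each in
#'   `[0, 1]`, summing to > 0.
#' @param p1,p2,p3 per-size probabilities in `[0, 1]`.
#' @param normalize divide by the weight sum (default TRUE).
#' @return fused probability.
#' @export
fuseProbabilities <- function(weights, p1, p2, p3, normalize = TRUE) {
  l <- c(weights$lambda1, weights$lambda2, weights$lambda3)
  if (any(l < 0 | l > 1)) stop("weights must lie in [0, 1]")
  if (sum(l) <= 0) stop("weight sum must be > 0")
  p <- c(p1, p2, p3)
  if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]")
  s <- l[1] * p1 + l[2] * p2 + l[3] * p3
  if (normalize) s / sum(l) else s
}

#' Classify candidates with the trained ensemble
#'
#' Computes the three per-size probabilities for every candidate, fuses them
#' and thresholds: candidates whose fused probability falls below the
#' decision threshold are the excluded false positives (a decision threshold
#' of 0 keeps everything).
#'
#' @param ensemble a [trainClassifierEnsemble()] result.
#' @param crops_per_candidate list of [cropMultiscale()] results (all three
#'   sizes present per candidate).
#' @param threshold decision threshold on the fused probability.
#' @param candidate_ids optional ids for the output table.
#' @return data.frame with `candidate_id`, `p1`, `p2`, `p3`, `p_fused`,
#'   `label` (1 = keep as fracture, 0 = excluded).
#' @export
classifyCandidates <- function(ensemble, crops_per_candidate, threshold = 0.5,
                               candidate_ids = NULL) {
  stopifnot(inherits(ensemble, "ClassifierEnsemble"))
  n <- length(crops_per_candidate)
  ids <- candidate_ids %||% vapply(seq_len(n), function(i) {
    c0 <- crops_per_candidate[[i]]
    if (inherits(c0, "MultiScaleCrops")) as.integer(c0$candidate_id) else i
  }, integer(1))
  out <- data.frame(candidate_id = ids, p1 = numeric(n), p2 = numeric(n),
                    p3 = numeric(n), p_fused = numeric(n), label = integer(n))
  for (i in seq_len(n)) {
    cand <- crops_per_candidate[[i]]
    crops <- if (inherits(cand, "MultiScaleCrops")) cand$crops else cand
    if (length(crops) != 3L) stop("candidate ", ids[i], " is missing a crop size")
    ps <- vapply(1:3, function(s) classifierProb(ensemble$models[[s]],
                                                 crops[[s]]), numeric(1))
    pf <- fuseProbabilities(ensemble$weights, ps[1], ps[2], ps[3])
    out[i, 2:6] <- c(ps, pf, as.integer(pf >= threshold))
  }
  out
}
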