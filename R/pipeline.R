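# End-to-end orchestration: simulate -> preprocess -> train-seg -> predict ->
# extract-candidates -> train-cls -> classify -> evaluate, with one global
# seed deriving every stage's RNG stream and a JSON manifest tying artifacts
# to the configuration.

.hashString <- function(x) {
  h <- 0
  for (code in utf8ToInt(x)) h <- (h * 131 + code) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Pipeline configuration
#'
#' Bundles the per-stage configurations and a single global seed; all module
#' seeds are derived from it by stage-name hashing.
#'
#' @param phantom a [phantomConfig()] (its own seed is overridden by the
#'   derived stage seed).
#' @param n_samples total phantoms; `val_fraction` of them are held out from
#'   all training and used for evaluation.
#' @param val_fraction held-out fraction.
#' @param unet a [unetConfig()] or preset name for [unetPreset()].
#' @param cascade optional [cascadeConfig()]; when given, prediction uses the
#'   fine model with the upsampled coarse probability as a second channel.
#' @param train a [trainConfig()] for the segmenter.
#' @param seg_loss a [lossConfig()].
#' @param threshold,overlap,connectivity,min_component_size stage-1 inference
#'   settings (binarization threshold, window overlap, component
#'   connectivity, minimum candidate size).
#' @param crop_sizes three strictly increasing cubic crop edge lengths.
#' @param cls_train a [trainConfig()] for the classifiers.
#' @param cls_growth,cls_blocks dense-net growth rate and block layout.
#' @param decision_threshold stage-2 decision threshold on the fused
#'   probability.
#' @param candidate_source `"mined"` (stage-2 training candidates are the
#'   segmenter's own proposals on the training volumes, topped up with
#'   ground-truth positives / random negatives if a class is missing) or
#'   `"gt_plus_random"` (ground-truth instances as positives plus random
#'   off-lesion crops as negatives).
#' @param seed global seed.
#' @return list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(phantom = phantomConfig(),
                           n_samples = 10, val_fraction = 0.3,
                           unet = "tiny", cascade = NULL,
                           train = trainConfig(),
                           seg_loss = lossConfig(),
                           threshold = 0.5, overlap = 0.5,
                           connectivity = 26, min_component_size = 1,
                           crop_sizes = c(48, 64, 80),
                           cls_train = trainConfig(),
                           cls_growth = 8, cls_blocks = c(2, 2),
                           decision_threshold = 0.5,
                           candidate_source = c("mined", "gt_plus_random"),
                           seed = 1) {
  if (is.character(unet)) unet <- unetPreset(unet)
  candidate_source <- match.arg(candidate_source)
  stopifnot(inherits(phantom, "PhantomConfig"), inherits(unet, "UNetConfig"),
            inherits(train, "TrainConfig"), inherits(cls_train, "TrainConfig"),
            n_samples >= 2, val_fraction > 0, val_fraction < 1,
            length(crop_sizes) == 3L)
  structure(list(phantom = phantom, n_samples = as.integer(n_samples),
                 val_fraction = val_fraction, unet = unet, cascade = cascade,
                 train = train, seg_loss = seg_loss, threshold = threshold,
                 overlap = overlap, connectivity = connectivity,
                 min_component_size = min_component_size,
                 crop_sizes = as.integer(crop_sizes), cls_train = cls_train,
                 cls_growth = cls_growth, cls_blocks = cls_blocks,
                 decision_threshold = decision_threshold,
                 candidate_source = candidate_source,
                 seed = as.integer(seed)), class = "PipelineConfig")
}

#' Desk-scale pipeline profile
#'
#' The default tiny profile used by the synthetic end-to-end experiment:
#' 20 phantoms of 64^3 voxels with 3 lesions and 2 decoy blobs each, a tiny
#' 3D segmenter (16^3 patches, 2 poolings, 4 base channels) and small
#' dense-net classifiers on 12/16/20-voxel crops.  Candidates below 10 voxels
#' (about a fifth of the smallest lesion volume) are dropped to keep the
#' stage-2 workload bounded on a single CPU.
#'
#' @param seed global seed.
#' @param n_samples phantom count.
#' @return a [pipelineConfig()].
#' @export
tinyPipelineConfig <- function(seed = 1, n_samples = 20) {
  pipelineConfig(
    phantom = phantomConfig(grid_size = c(64, 64, 64), n_ribs = 3,
                            n_lesions = 3, n_decoys = 2),
    n_samples = n_samples, val_fraction = 0.3,
    unet = unetConfig(3, c(16, 16, 16), c(2, 2, 2), base_channels = 4),
    train = trainConfig(batch_size = 2, epochs = 120, learning_rate = 1e-3,
                        fg_patch_fraction = 0.4, steps_per_epoch = 10),
    min_component_size = 10,
    crop_sizes = c(12, 16, 20),
    cls_train = trainConfig(batch_size = 2, epochs = 15,
                            learning_rate = 5e-3),
    cls_growth = 8, cls_blocks = c(2, 2),
    seed = seed)
}

.stageRun <- function(manifest, name, verbose, expr) {
  if (verbose) message("[", name, "] running ...")
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(force(expr), error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
  manifest$stages[[name]] <- list(status = "ok",
                                  seconds = round(proc.time()[["elapsed"]] - t0, 2))
  if (verbose) message("[", name, "] done (",
                       manifest$stages[[name]]$seconds, " s)")
  list(manifest = manifest, value = res)
}

#' Run the full two-stage pipeline
#'
#' Executes simulate, preprocess, train-seg, predict, extract-candidates,
#' train-cls, classify and evaluate in order, writing phantom NIfTI pairs,
#' the dataset fingerprint, candidate tables, decision tables and a manifest
#' (config hash, derived seeds, per-stage timings, final reports) under
#' `workdir`.  A failing stage aborts with the stage name.  Identical config
#' and seed give identical manifest metrics.
#'
#' @param config a [pipelineConfig()].
#' @param workdir writable working directory (created if needed).
#' @param verbose print stage progress.
#' @return the manifest, invisibly also written to
#'   `file.path(workdir, "manifest.json")`.
#' @export
runPipeline <- function(config, workdir, verbose = FALSE) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(workdir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  manifest <- list(config_hash = .hashString(jsonlite::toJSON(
                     list(n = config$n_samples, seed = seed,
                          grid = config$phantom$grid_size,
                          crops = config$crop_sizes), auto_unbox = TRUE)),
                   seed = seed, stages = list())

  ## simulate ---------------------------------------------------------------
  phantom_cfg <- config$phantom
  phantom_cfg$seed <- deriveSeed(seed, "simulate")
  raw_dir <- file.path(workdir, "raw")
  dir.create(raw_dir, showWarnings = FALSE)
  st <- .stageRun(manifest, "simulate", verbose, {
    samples <- generateDataset(phantom_cfg, config$n_samples)
    for (i in seq_along(samples))
      writeSample(samples[[i]],
                  file.path(raw_dir, sprintf("s%03d_image.nii.gz", i - 1L)),
                  file.path(raw_dir, sprintf("s%03d_label.nii.gz", i - 1L)),
                  file.path(raw_dir, sprintf("s%03d_catalogue.json", i - 1L)))
    samples
  })
  manifest <- st$manifest

  n <- config$n_samples
  n_val <- max(1L, round(config$val_fraction * n))
  val_idx <- withSeed(deriveSeed(seed, "split"), sample.int(n, n_val))
  train_idx <- setdiff(seq_len(n), val_idx)
  manifest$split <- list(train = train_idx, val = val_idx)

  ## preprocess (round-trips through the NIfTI files on disk) ---------------
  st <- .stageRun(manifest, "preprocess", verbose, {
    raw <- lapply(seq_len(n) - 1L, function(i) {
      list(image = readVolume(file.path(raw_dir, sprintf("s%03d_image.nii.gz", i)),
                              "image"),
           labels = readVolume(file.path(raw_dir, sprintf("s%03d_label.nii.gz", i)),
                               "label"))
    })
    fp <- computeFingerprint(raw[train_idx])
    writeFingerprint(fp, file.path(workdir, "fingerprint.json"))
    list(fp = fp, pre = lapply(raw, preprocessSample, fingerprint = fp))
  })
  manifest <- st$manifest
  fp <- st$value$fp
  pre <- st$value$pre
  manifest$fingerprint <- unclass(fp)

  ## train-seg ---------------------------------------------------------------
  train_cfg <- config$train
  train_cfg$seed <- deriveSeed(seed, "train-seg")
  st <- .stageRun(manifest, "train-seg", verbose, {
    if (is.null(config$cascade)) {
      trainSegmenter(pre[train_idx], config$unet, train_cfg, config$seg_loss)
    } else {
      trainCascade(pre[train_idx], config$cascade, train_cfg, config$seg_loss)
    }
  })
  manifest <- st$manifest
  seg <- st$value
  history <- if (is.null(config$cascade)) seg$history else seg$fine_history
  manifest$loss_history <- history

  predictOne <- function(s) {
    if (is.null(config$cascade)) {
      plan <- planWindows(geometry(s$image), config$unet$patch_size,
                          config$overlap)
      predictVolume(seg$model, s$image, plan)
    } else {
      cimg <- resampleVolume(s$image, seg$coarse_spacing_mm, "continuous")
      cplan <- planWindows(geometry(cimg), config$cascade$coarse$patch_size,
                           config$overlap)
      cf <- predictVolume(seg$coarse, cimg, cplan)
      cp <- ProbabilityVolume(pmin(pmax(cf$values, 0), 1),
                              geometry = geometry(cimg))
      up <- resampleVolume(cp, spacingMm(s$image), "continuous")
      uv <- .cropPad(voxelData(up), c(1L, 1L, 1L), dim(voxelData(s$image)), 0)
      extra <- ProbabilityVolume(pmin(pmax(uv, 0), 1),
                                 geometry = geometry(s$image))
      plan <- planWindows(geometry(s$image), config$cascade$fine$patch_size,
                          config$overlap)
      predictVolume(seg$fine, s$image, plan, extra = extra)
    }
  }

  ## predict + extract-candidates --------------------------------------------
  st <- .stageRun(manifest, "predict", verbose, lapply(pre, predictOne))
  manifest <- st$manifest
  fused <- st$value

  st <- .stageRun(manifest, "extract-candidates", verbose, {
    lapply(fused, extractCandidates, threshold = config$threshold,
           connectivity = config$connectivity,
           min_component_size = config$min_component_size)
  })
  manifest <- st$manifest
  cands <- st$value

  ## train-cls ----------------------------------------------------------------
  cls_train <- config$cls_train
  cls_train$seed <- deriveSeed(seed, "train-cls")
  st <- .stageRun(manifest, "train-cls", verbose, {
    mined <- .collectTrainingCandidates(config, pre, cands, train_idx,
                                        deriveSeed(seed, "cls-mine"))
    configs <- lapply(config$crop_sizes, function(s)
      denseNetConfig(s, growth_rate = config$cls_growth,
                     block_layout = config$cls_blocks))
    ens <- trainClassifierEnsemble(mined$crops, mined$labels, configs,
                                   cls_train)
    list(ensemble = ens, n_pos = sum(mined$labels == 1),
         n_neg = sum(mined$labels == 0))
  })
  manifest <- st$manifest
  ensemble <- st$value$ensemble
  manifest$fusion_weights <- ensemble$weights
  manifest$cls_training <- list(n_pos = st$value$n_pos, n_neg = st$value$n_neg)

  ## classify (held-out volumes) ----------------------------------------------
  st <- .stageRun(manifest, "classify", verbose, {
    lapply(val_idx, function(i) {
      tab <- candidateTable(cands[[i]])
      if (!nrow(tab)) return(data.frame())
      crops <- lapply(seq_len(nrow(tab)), function(r)
        cropMultiscale(pre[[i]]$image, tab[r, ], config$crop_sizes))
      dec <- classifyCandidates(ensemble, crops, config$decision_threshold)
      utils::write.csv(dec, file.path(workdir,
        sprintf("decisions_s%03d.csv", i - 1L)), row.names = FALSE)
      dec
    })
  })
  manifest <- st$manifest
  decisions <- st$value

  ## evaluate -----------------------------------------------------------------
  st <- .stageRun(manifest, "evaluate", verbose, {
    agg <- function(reports) {
      s <- function(f) sum(vapply(reports, `[[`, numeric(1), f))
      nt <- s("n_truth_instances"); nd <- s("n_detected")
      np <- s("n_predictions"); nf <- s("n_false_positive_predictions")
      list(n_truth_instances = nt, n_detected = nd, n_predictions = np,
           n_false_positive_predictions = nf,
           recognition_rate = if (nt > 0) nd / nt else NA_real_,
           fp_rate = if (np > 0) nf / np else 0)
    }
    stage1 <- list(); stage2 <- list(); segrep <- list()
    for (j in seq_along(val_idx)) {
      i <- val_idx[j]
      truth <- pre[[i]]$labels
      stage1[[j]] <- detectionReport(cands[[i]], truth)
      acc_ids <- if (nrow(decisions[[j]]))
        decisions[[j]]$candidate_id[decisions[[j]]$label == 1L] else integer(0)
      stage2[[j]] <- detectionReport(cands[[i]], truth, accepted_ids = acc_ids)
      pm <- BinaryMask(array(as.integer(fused[[i]]$values > config$threshold),
                             dim = dim(voxelData(truth))),
                       geometry = geometry(truth))
      segrep[[j]] <- suppressWarnings(
        segmentationReport(pm, mergeLabels(truth)))
    }
    list(stage1 = agg(stage1), stage2 = agg(stage2),
         segmentation = list(
           mean_dice = mean(vapply(segrep, `[[`, numeric(1), "dice")),
           mean_iou = mean(vapply(segrep, `[[`, numeric(1), "iou"))))
  })
  manifest <- st$manifest
  manifest$report <- st$value

  jsonlite::write_json(manifest, file.path(workdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}

# Assemble labelled stage-2 training crops from the training volumes.
.collectTrainingCandidates <- function(config, pre, cands, train_idx, seed) {
  crops <- list(); labels <- integer(0)
  addCand <- function(i, row, lab) {
    crops[[length(crops) + 1L]] <<- cropMultiscale(pre[[i]]$image, row,
                                                   config$crop_sizes)
    labels <<- c(labels, lab)
  }
  truthRows <- function(i) {
    tm <- voxelData(pre[[i]]$mask)
    d <- dim(tm)
    comp <- .label_components(array(as.integer(tm), dim = d), d, 26L)
    k <- max(comp)
    if (!k) return(NULL)
    idx <- which(comp > 0L); co <- arrayInd(idx, d); ids <- comp[idx]
    do.call(rbind, lapply(seq_len(k), function(cid) {
      cc <- co[ids == cid, , drop = FALSE]
      data.frame(component_id = -cid, z_c = mean(cc[, 1]), y_c = mean(cc[, 2]),
                 x_c = mean(cc[, 3]))
    }))
  }
  randomNegRow <- function(i) {
    tm <- voxelData(pre[[i]]$mask)
    d <- dim(tm)
    for (try in 1:50) {
      v <- vapply(d, function(m) sample.int(m, 1L), integer(1))
      if (tm[v[1], v[2], v[3]] == 0L)
        return(data.frame(component_id = 0L, z_c = v[1], y_c = v[2], x_c = v[3]))
    }
    NULL
  }
  withSeed(seed, {
    if (config$candidate_source == "mined") {
      for (i in train_idx) {
        tab <- labelCandidates(cands[[i]], pre[[i]]$mask)
        if (nrow(tab))
          for (r in seq_len(nrow(tab))) addCand(i, tab[r, ], tab$label[r])
      }
      # top up a missing class so stage-2 training stays well-posed
      if (sum(labels == 1L) < 2L)
        for (i in train_idx) {
          tr <- truthRows(i)
          if (!is.null(tr)) for (r in seq_len(nrow(tr))) addCand(i, tr[r, ], 1L)
        }
      if (sum(labels == 0L) < 2L)
        for (i in train_idx) {
          nr <- randomNegRow(i)
          if (!is.null(nr)) addCand(i, nr, 0L)
        }
    } else {
      for (i in train_idx) {
        tr <- truthRows(i)
        n_pos_i <- if (is.null(tr)) 0L else nrow(tr)
        if (n_pos_i) for (r in seq_len(n_pos_i)) addCand(i, tr[r, ], 1L)
        for (j in seq_len(max(1L, n_pos_i))) {
          nr <- randomNegRow(i)
          if (!is.null(nr)) addCand(i, nr, 0L)
        }
      }
    }
  })
  list(crops = crops, labels = labels)
}
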