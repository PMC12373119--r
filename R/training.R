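# Adversarial training loop: per batch one discriminator update followed by
# one generator update (model variants 1 and 2) or two generator updates
# (variant 3, the "generator iteration" that strengthens the generator
# against the discriminator), plus the fine-tuning protocol for new
# differentiation batches.

#' Training configuration
#'
#' @param epochs passes over the training set.
#' @param batchSize images per update step.
#' @param lrG,lrD Adam learning rates for generator and discriminator.
#' @param beta1,beta2 Adam momentum coefficients.
#' @param lambda weight of the L1 reconstruction term.
#' @param modelVariant 1 = plain U-Net, 2 = U-Net + CBAM,
#'   3 = U-Net + CBAM with doubled generator updates per batch.
#' @param baseG,baseD base channel widths of generator and discriminator
#'   (desk-scale defaults; 64 reproduces the full-scale backbone).
#' @param depth generator depth, `NULL` for log2(image size).
#' @param discCondition `TRUE` to feed the discriminator the Lightness
#'   condition stacked with a*b* (standard conditional-GAN practice),
#'   `FALSE` for the ab-only variant.
#' @param cbamReduction CBAM channel-attention reduction ratio.
#' @param seed master seed; initialization and batch shuffling derive from
#'   it, so identical config + data reproduce the run exactly.
#' @return A list of class `"trainingConfig"`.
#' @export
trainingConfig <- function(epochs = 20L, batchSize = 8L, lrG = 2e-4,
                           lrD = 2e-4, beta1 = 0.5, beta2 = 0.999,
                           lambda = 100, modelVariant = 2L, baseG = 16L,
                           baseD = 16L, depth = NULL, discCondition = TRUE,
                           cbamReduction = 16L, seed = 1L) {
  if (batchSize < 1L) stop("batchSize must be >= 1")
  if (lambda < 0) stop("lambda must be non-negative")
  if (!modelVariant %in% 1:3) stop("modelVariant must be 1, 2 or 3")
  structure(list(epochs = as.integer(epochs), batchSize = as.integer(batchSize),
                 lrG = lrG, lrD = lrD, beta1 = beta1, beta2 = beta2,
                 lambda = lambda, modelVariant = as.integer(modelVariant),
                 baseG = as.integer(baseG), baseD = as.integer(baseD),
                 depth = depth, discCondition = isTRUE(discCondition),
                 cbamReduction = as.integer(cbamReduction),
                 seed = as.integer(seed)),
            class = "trainingConfig")
}

.asRgbArray <- function(x) {
  if (is(x, "RgbImage")) unclass(x) else x
}

# one paired sample -> (condition plane, target ab planes), both in [-1, 1]
.pairTensors <- function(phase, fluor) {
  lab <- normalizeLab(rgbToLab(.asRgbArray(phase)), "forward")
  flab <- normalizeLab(rgbToLab(.asRgbArray(fluor)), "forward")
  list(cond = labL(lab), a = labA(flab), b = labB(flab))
}

# dataset: list of list(phase=, fluor=) pairs, or a manifest data frame with
# phase_path / fluor_path columns
.datasetTensors <- function(dataset) {
  if (is.data.frame(dataset)) {
    dataset <- lapply(seq_len(nrow(dataset)), function(i)
      list(phase = readRgbPng(dataset$phase_path[i]),
           fluor = readRgbPng(dataset$fluor_path[i])))
  }
  n <- length(dataset)
  if (n < 1L) stop("training needs at least one paired sample")
  dims <- t(vapply(dataset, function(p) dim(.asRgbArray(p$phase))[1:2],
                   numeric(2)))
  if (nrow(unique(dims)) != 1L)
    stop("image sizes are inconsistent across the dataset")
  H <- dims[1, 1]; W <- dims[1, 2]
  for (p in dataset)
    if (!identical(dim(.asRgbArray(p$fluor))[1:2], as.integer(c(H, W))) &&
        !identical(dim(.asRgbArray(p$fluor))[1:2], c(H, W)))
      stop("phase and fluorescence images differ in size")
  cond <- array(0, c(1L, H, W, n))
  target <- array(0, c(2L, H, W, n))
  for (i in seq_len(n)) {
    tt <- .pairTensors(dataset[[i]]$phase, dataset[[i]]$fluor)
    cond[1L, , , i] <- tt$cond
    target[1L, , , i] <- tt$a
    target[2L, , , i] <- tt$b
  }
  list(cond = cond, target = target, n = n, size = H)
}

.sub4 <- function(x, ids) x[, , , ids, drop = FALSE]

.trainLoop <- function(gen, disc, data, config, epochs, history0 = NULL,
                       counts0 = c(g = 0L, d = 0L)) {
  gCells <- .netParamCells(gen)
  dCells <- .netParamCells(disc)
  gIter <- if (config$modelVariant == 3L) 2L else 1L
  useCond <- config$discCondition
  lam <- config$lambda
  rows <- list()
  gStep <- counts0[["g"]]; dStep <- counts0[["d"]]
  for (ep in seq_len(epochs)) {
    ord <- sample(data$n)
    starts <- seq(1L, data$n, by = config$batchSize)
    for (s in starts) {
      ids <- ord[s:min(s + config$batchSize - 1L, data$n)]
      xc <- .sub4(data$cond, ids)
      xt <- .sub4(data$target, ids)
      condIn <- if (useCond) xc else NULL
      # --- discriminator update
      fake <- .genForward(gen, xc)
      .zeroGrads(dCells)
      zr <- .discForwardLogits(disc, .discInput(condIn, xt))
      br <- .bceWithLogits(zr, 1)
      .discBackward(disc, br$grad)
      zf <- .discForwardLogits(disc, .discInput(condIn, fake))
      bf <- .bceWithLogits(zf, 0)
      .discBackward(disc, bf$grad)
      dStep <- dStep + 1L
      .adamStep(dCells, config$lrD, config$beta1, config$beta2, 1e-8, dStep)
      lossD <- br$loss + bf$loss
      # --- generator update(s)
      lossAdv <- lossL1 <- NA_real_
      for (it in seq_len(gIter)) {
        fake <- .genForward(gen, xc)
        .zeroGrads(gCells)
        .zeroGrads(dCells)
        zf <- .discForwardLogits(disc, .discInput(condIn, fake))
        badv <- .bceWithLogits(zf, 1)
        dIn <- .discBackward(disc, badv$grad)
        dab <- if (useCond) dIn[-1L, , , , drop = FALSE] else dIn
        dfake <- dab + lam * sign(fake - xt) / length(fake)
        .genBackward(gen, dfake)
        gStep <- gStep + 1L
        .adamStep(gCells, config$lrG, config$beta1, config$beta2, 1e-8, gStep)
        lossAdv <- badv$loss
        lossL1 <- mean(abs(fake - xt))
      }
      rows[[length(rows) + 1L]] <-
        data.frame(epoch = ep, dStep = dStep, gStep = gStep,
                   lossD = lossD, lossAdv = lossAdv, lossL1 = lossL1)
    }
  }
  history <- do.call(rbind, rows)
  if (!is.null(history0)) {
    history$epoch <- history$epoch + max(history0$epoch)
    history <- rbind(history0, history)
  }
  list(history = history, counts = c(g = gStep, d = dStep))
}

#' Train the colorization GAN
#'
#' Runs adversarial training of the Lightness-conditioned U-Net generator
#' against the patch discriminator with the combined adversarial + lambda*L1
#' generator objective.  Model variant 1 disables CBAM; variants 2 and 3
#' enable it; variant 3 performs two generator updates per discriminator
#' update.  Fully reproducible given the config seed.
#'
#' @param dataset a list of pairs `list(phase =, fluor =)` of
#'   [RgbImage-class] objects (or H x W x 3 arrays), or a manifest
#'   `data.frame` with `phase_path` / `fluor_path` columns.
#' @param config a [trainingConfig()].
#' @return A checkpoint object (list, class `"coCheckpoint"`) holding the
#'   trained parameters, configs, per-step loss history and update counters.
#' @export
trainColorizer <- function(dataset, config = trainingConfig()) {
  data <- .datasetTensors(dataset)
  if (!.isPow2(data$size))
    stop("training images must have power-of-two size")
  .withSeed(config$seed, {
    gen <- buildGenerator(data$size, base = config$baseG,
                          depth = config$depth,
                          cbam = config$modelVariant >= 2L,
                          cbamReduction = config$cbamReduction,
                          seed = config$seed)
    disc <- buildDiscriminator(if (config$discCondition) 3L else 2L,
                               base = config$baseD, seed = config$seed + 1L)
    res <- .trainLoop(gen, disc, data, config, config$epochs)
    structure(list(schema = "organoColor-checkpoint-1",
                   size = data$size,
                   generatorConfig = gen@config,
                   generatorParams = .netSnapshot(gen),
                   discConfig = disc@config,
                   discParams = .netSnapshot(disc),
                   trainConfig = config,
                   history = res$history,
                   counts = res$counts),
              class = "coCheckpoint")
  })
}

#' Rebuild the trained generator from a checkpoint
#' @param checkpoint a `"coCheckpoint"` object.
#' @return A [GeneratorNet-class] with the stored parameters.
#' @export
restoreGenerator <- function(checkpoint) {
  cfg <- checkpoint$generatorConfig
  gen <- buildGenerator(cfg$size, base = cfg$base, depth = cfg$depth,
                        cbam = cfg$cbam, cbamReduction = cfg$cbamReduction,
                        seed = cfg$seed)
  .netRestore(gen, checkpoint$generatorParams)
}

.restoreDiscriminator <- function(checkpoint) {
  cfg <- checkpoint$discConfig
  disc <- buildDiscriminator(cfg$inChannels, base = cfg$base, seed = cfg$seed)
  .netRestore(disc, checkpoint$discParams)
}

#' Fine-tune a trained model on a new differentiation batch
#'
#' Continues adversarial training on a mixture of the original training
#' pairs and `floor(fraction * length(newPairs))` images drawn (seeded,
#' without replacement) from the new batch; the remaining new-batch images
#' never enter training and stay available as a held-out evaluation set.
#' The original learning rates are kept unless a new config is supplied.
#'
#' @param checkpoint a `"coCheckpoint"` from [trainColorizer()].
#' @param newPairs pairs from the new batch (same format as `dataset` in
#'   [trainColorizer()]).
#' @param originalPairs the original training pairs.
#' @param fraction fraction of the new batch entering the pool, in (0, 1];
#'   1/3 reproduces the published protocol, 1 degenerates to ordinary
#'   continued training.
#' @param epochs fine-tuning epochs (default: the checkpoint's epoch count).
#' @param seed seed for the new-batch draw and shuffling (default: original
#'   seed + 1).
#' @return An updated `"coCheckpoint"`; `$fineTuneIdx` records which
#'   new-batch images entered the pool.
#' @export
fineTune <- function(checkpoint, newPairs, originalPairs, fraction = 1 / 3,
                     epochs = NULL, seed = NULL) {
  if (!inherits(checkpoint, "coCheckpoint"))
    stop("not a checkpoint object")
  if (fraction <= 0 || fraction > 1)
    stop("fraction must lie in (0, 1]")
  if (is.data.frame(newPairs))
    newPairs <- lapply(seq_len(nrow(newPairs)), function(i)
      list(phase = readRgbPng(newPairs$phase_path[i]),
           fluor = readRgbPng(newPairs$fluor_path[i])))
  config <- checkpoint$trainConfig
  seed <- as.integer(seed %||% (config$seed + 1L))
  epochs <- as.integer(epochs %||% config$epochs)
  nNew <- length(newPairs)
  k <- floor(fraction * nNew)
  if (k < 1L) stop("fraction * new-batch size selects no image")
  .withSeed(seed, {
    idx <- sort(sample(nNew, k))
    pool <- c(if (is.data.frame(originalPairs))
                .manifestPairs(originalPairs) else originalPairs,
              newPairs[idx])
    data <- .datasetTensors(pool)
    gen <- restoreGenerator(checkpoint)
    disc <- .restoreDiscriminator(checkpoint)
    res <- .trainLoop(gen, disc, data, config, epochs,
                      history0 = checkpoint$history,
                      counts0 = checkpoint$counts)
    out <- checkpoint
    out$generatorParams <- .netSnapshot(gen)
    out$discParams <- .netSnapshot(disc)
    out$history <- res$history
    out$counts <- res$counts
    out$fineTuneIdx <- idx
    out
  })
}

.manifestPairs <- function(df) {
  lapply(seq_len(nrow(df)), function(i)
    list(phase = readRgbPng(df$phase_path[i]),
         fluor = readRgbPng(df$fluor_path[i])))
}

#' Save / load a checkpoint
#' @param checkpoint a `"coCheckpoint"`.
#' @param path file path.
#' @export
saveCheckpoint <- function(checkpoint, path) {
  if (!inherits(checkpoint, "coCheckpoint")) stop("not a checkpoint object")
  saveRDS(checkpoint, path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$schema, "organoColor-checkpoint-1"))
    stop("unrecognized checkpoint schema")
  ck
}
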