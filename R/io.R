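# PNG and manifest plumbing, prediction and evaluation orchestration.

#' Read a 24-bit PNG as an RgbImage
#'
#' Grayscale PNGs are expanded to three equal channels; an alpha channel is
#' dropped.
#'
#' @param path PNG file path.
#' @return An [RgbImage-class].
#' @export
readRgbPng <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 2L) x <- array(rep(x, 3L), c(dim(x), 3L))
  if (dim(x)[3] == 4L) x <- x[, , 1:3, drop = FALSE]
  RgbImage(round(x * 255))
}

#' Write an RgbImage as a 24-bit PNG
#'
#' @param img an [RgbImage-class] (or H x W x 3 array in [0, 255]).
#' @param path destination path.
#' @export
writeRgbPng <- function(img, path) {
  px <- .asRgbArray(img)
  png::writePNG(px / 255, path)
  invisible(path)
}

#' Read and validate a dataset manifest
#'
#' @param path CSV with columns `id`, `phase_path`, `fluor_path`, `split`
#'   and `batch_tag`.
#' @return The manifest data.frame.
#' @export
readManifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "phase_path", "fluor_path", "split", "batch_tag")
  miss <- setdiff(need, names(m))
  if (length(miss)) stop("manifest misses columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(m$id)) stop("manifest ids are not unique")
  gone <- !file.exists(m$phase_path) | !file.exists(m$fluor_path)
  if (any(gone)) stop("missing image files for ids: ",
                      paste(m$id[gone], collapse = ", "))
  m
}

#' Colorize phase-contrast images with a trained model
#'
#' For each image: the Lightness plane of the phase image is extracted and
#' normalized, the generator predicts the chromatic a*/b* planes, these are
#' denormalized and merged onto the original (unnormalized) Lightness plane,
#' and the merged CIELAB image is converted back to 8-bit RGB.  Only a* and
#' b* are generated, so the output preserves the input's grayscale content.
#'
#' @param checkpoint a `"coCheckpoint"` from [trainColorizer()], or a
#'   [GeneratorNet-class] directly.
#' @param phase a single [RgbImage-class], a list of them, or a character
#'   vector of PNG paths.
#' @return An [RgbImage-class] (single input) or list of them.
#' @export
predictColors <- function(checkpoint, phase) {
  gen <- if (is(checkpoint, "GeneratorNet")) checkpoint
         else restoreGenerator(checkpoint)
  one <- function(img) {
    if (is.character(img)) img <- readRgbPng(img)
    px <- .asRgbArray(img)
    if (nrow(px) != gen@config$size)
      stop("checkpoint was trained on ", gen@config$size, " px images, got ",
           nrow(px))
    lab <- rgbToLab(px)
    Ln <- labL(lab) / 50 - 1
    out <- generatorForward(gen, Ln)
    labToRgb(mergeLightness(labL(lab), out[1, , ] * 128, out[2, , ] * 128))
  }
  if (is(phase, "RgbImage")) return(one(phase))
  if (is.character(phase) && length(phase) == 1L) return(one(phase))
  lapply(phase, one)
}

.fmtPsnr <- function(x) ifelse(is.infinite(x), "inf", format(x, digits = 8))

#' Evaluate a trained model over the test split of a manifest
#'
#' Predicts every test pair, computes PSNR, SSIM and WPH plus the
#' per-channel quantification difference%, and aggregates means over the
#' test set.
#'
#' @param manifest manifest data.frame (see [readManifest()]) or CSV path.
#' @param checkpoint a `"coCheckpoint"`.
#' @param cfg a [wphConfig()] (patch size must divide the image size).
#' @param threshold quantification mask threshold (see [measureChannel()]).
#' @param outDir if non-NULL, `per_image.csv` and `aggregate.csv` are
#'   written there (infinite PSNR appears as the string "inf").
#' @param split which manifest split to evaluate (default "test").
#' @return list with `perImage` and `aggregate` data.frames.
#' @export
evaluateRun <- function(manifest, checkpoint, cfg = wphConfig(),
                        threshold = 10, outDir = NULL, split = "test") {
  if (is.character(manifest)) manifest <- readManifest(manifest)
  rows <- manifest[manifest$split == split, , drop = FALSE]
  if (nrow(rows) == 0L) stop("no rows in split '", split, "'")
  gen <- restoreGenerator(checkpoint)
  per <- lapply(seq_len(nrow(rows)), function(i) {
    pred <- predictColors(gen, rows$phase_path[i])
    gt <- readRgbPng(rows$fluor_path[i])
    rep <- evaluatePair(pred, gt, cfg)
    q <- quantifyPair(pred, gt, threshold)
    qv <- stats::setNames(q$differencePct,
                          paste0("diff_", q$channel, "_", q$metric))
    c(list(id = rows$id[i], psnr = psnrValue(rep), ssim = ssimValue(rep),
           wph = wphValue(rep)), as.list(qv))
  })
  perImage <- do.call(rbind, lapply(per, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  num <- vapply(perImage, is.numeric, logical(1))
  aggregate <- as.data.frame(as.list(colMeans(perImage[num], na.rm = TRUE)))
  if (!is.null(outDir)) {
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    pi2 <- perImage; pi2$psnr <- .fmtPsnr(pi2$psnr)
    ag2 <- aggregate; ag2$psnr <- .fmtPsnr(ag2$psnr)
    utils::write.csv(pi2, file.path(outDir, "per_image.csv"), row.names = FALSE)
    utils::write.csv(ag2, file.path(outDir, "aggregate.csv"), row.names = FALSE)
  }
  list(perImage = perImage, aggregate = aggregate)
}
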