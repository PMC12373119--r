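# Per-channel fluorescence quantification: the Organalysis-style
# measurements (area, coverage, intensity and intensity ratios) and the
# difference% comparison between generated and ground-truth images.

#' Split an RGB image into its single-channel planes
#'
#' Lossless channel extraction with the reporter roles of the organoid
#' system attached: R carries the mOrange endothelial-cell (EC) signal and
#' G the GFP cardiomyocyte (CM) signal.
#'
#' @param img an [RgbImage-class] (or H x W x 3 array).
#' @return Named list of three H x W matrices `R`, `G`, `B`, with a
#'   `roles` attribute (`R = "mOrange-EC"`, `G = "GFP-CM"`, `B = ""`).
#' @export
splitChannels <- function(img) {
  px <- .asRgbArray(img)
  if (length(dim(px)) != 3L || dim(px)[3] != 3L)
    stop("splitChannels() needs a 3-channel image")
  d <- dim(px)
  out <- list(R = matrix(px[, , 1], d[1], d[2]),
              G = matrix(px[, , 2], d[1], d[2]),
              B = matrix(px[, , 3], d[1], d[2]))
  attr(out, "roles") <- c(R = "mOrange-EC", G = "GFP-CM", B = "")
  out
}

#' Measure one fluorescence channel
#'
#' The organoid mask is the set of pixels strictly above the threshold `T`
#' (a pixel exactly equal to `T` is background).  Organoid area is the mask
#' pixel count; total intensity sums the plane over the mask only, so
#' intensity-by-area is self-consistent.  When the mask is empty the
#' per-area ratio is undefined and reported as `NA`, never 0.
#'
#' @param plane single-channel 8-bit matrix (values 0-255).
#' @param threshold 8-bit threshold `T` (default 10, suppressing camera
#'   noise; 0 counts any nonzero pixel).
#' @param channel label stored in the result ("R", "G" or "B").
#' @return A [ChannelMeasurements-class].
#' @export
measureChannel <- function(plane, threshold = 10, channel = "G") {
  if (!is.matrix(plane)) stop("plane must be a single-channel matrix")
  if (min(plane) < 0 || max(plane) > 255)
    stop("plane values must lie in [0, 255]")
  mask <- plane > threshold
  area <- sum(mask)
  total <- sum(plane[mask])
  imgArea <- length(plane)
  new("ChannelMeasurements",
      organoidArea = area,
      pctCoverage = 100 * area / imgArea,
      totalIntensity = total,
      intensityByArea = if (area > 0) total / area else NA_real_,
      intensityByImageArea = total / imgArea,
      threshold = threshold,
      channel = channel)
}

.measurementVector <- function(m) {
  c(organoidArea = m@organoidArea,
    pctCoverage = m@pctCoverage,
    totalIntensity = m@totalIntensity,
    intensityByArea = m@intensityByArea,
    intensityByImageArea = m@intensityByImageArea)
}

#' Difference% between generated and ground-truth measurements
#'
#' Per measurement, 100 * |generated - ground truth| / ground truth, with
#' the low/high classification at the 25% boundary used to color the
#' published comparison tables (<= 25% is "low").  A ground-truth value of 0
#' yields an undefined (`NA`) difference, never infinity.
#'
#' @param gen [ChannelMeasurements-class] of the generated image.
#' @param gt [ChannelMeasurements-class] of the ground truth.
#' @return data.frame with columns `metric`, `generated`, `groundTruth`,
#'   `differencePct` and `classification` ("low", "high" or `NA`).
#' @export
differencePct <- function(gen, gt) {
  g <- .measurementVector(gen)
  t0 <- .measurementVector(gt)
  diff <- ifelse(is.na(g) | is.na(t0) | t0 == 0, NA_real_,
                 100 * abs(g - t0) / t0)
  data.frame(metric = names(g),
             generated = unname(g),
             groundTruth = unname(t0),
             differencePct = unname(diff),
             classification = ifelse(is.na(diff), NA_character_,
                                     ifelse(diff <= 25, "low", "high")),
             row.names = NULL)
}

#' Quantify both reporter channels of a generated/ground-truth pair
#'
#' Convenience wrapper: splits both images, measures the red (mOrange-EC)
#' and green (GFP-CM) channels and tabulates the difference%.
#'
#' @param gen,gt [RgbImage-class] objects.
#' @param threshold 8-bit mask threshold passed to [measureChannel()].
#' @return data.frame with one row per channel and measurement.
#' @export
quantifyPair <- function(gen, gt, threshold = 10) {
  sg <- splitChannels(gen); st <- splitChannels(gt)
  out <- lapply(c("R", "G"), function(ch) {
    d <- differencePct(measureChannel(sg[[ch]], threshold, ch),
                       measureChannel(st[[ch]], threshold, ch))
    cbind(channel = ch,
          role = unname(attr(sg, "roles")[ch]), d)
  })
  do.call(rbind, out)
}
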