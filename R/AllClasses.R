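#' @useDynLib organoColor, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
NULL

#' 24-bit RGB image
#'
#' An H x W x 3 array of 8-bit intensities (0-255 per channel), the external
#' interchange format of the package: phase-contrast inputs, fluorescence
#' ground truth and colorized predictions are all `RgbImage` objects.
#' Channel order is R, G, B; in the organoid reporter system the red channel
#' carries the mOrange endothelial-cell (EC) signal and the green channel the
#' GFP cardiomyocyte (CM) signal.
#'
#' @slot .Data numeric H x W x 3 array with integral values in [0, 255].
#' @export
setClass("RgbImage", contains = "array", validity = function(object) {
  d <- dim(object)
  if (length(d) != 3L || d[3] != 3L)
    return("an RgbImage must be an H x W x 3 array")
  if (anyNA(object) || any(!is.finite(object)))
    return("pixel values must be finite")
  if (min(object) < 0 || max(object) > 255)
    return("pixel values must lie in [0, 255]")
  if (any(object != round(object)))
    return("pixel values must be integral 8-bit counts")
  TRUE
})

#' Construct an RgbImage
#'
#' @param pixels H x W x 3 array of intensities in [0, 255].
#' @return An [RgbImage-class] object.
#' @export
RgbImage <- function(pixels) {
  new("RgbImage", array(as.numeric(pixels), dim = dim(pixels)))
}

setMethod("show", "RgbImage", function(object) {
  d <- dim(object)
  cat(sprintf("RgbImage %d x %d, range [%d, %d]\n",
              d[1], d[2], min(object), max(object)))
})

#' CIELAB image
#'
#' Holds the three CIELAB planes of an image.  In the unnormalized state L*
#' lies in [0, 100] and a*, b* in [-128, 127]; in the normalized state used
#' for network training all three planes lie in [-1, 1]
#' (see [normalizeLab()]).
#'
#' @slot L numeric matrix, the Lightness plane.
#' @slot a numeric matrix, the green-red chromatic plane.
#' @slot b numeric matrix, the blue-yellow chromatic plane.
#' @slot normalized logical flag selecting which range contract applies.
#' @export
setClass("LabImage",
  representation(L = "matrix", a = "matrix", b = "matrix",
                 normalized = "logical"),
  validity = function(object) {
    d <- dim(object@L)
    if (!identical(d, dim(object@a)) || !identical(d, dim(object@b)))
      return("L, a, b planes must share dimensions")
    if (length(object@normalized) != 1L)
      return("normalized must be a single flag")
    if (anyNA(object@L) || anyNA(object@a) || anyNA(object@b))
      return("Lab planes must be finite")
    if (object@normalized) {
      rng <- range(object@L, object@a, object@b)
      if (rng[1] < -1 - 1e-9 || rng[2] > 1 + 1e-9)
        return("normalized Lab planes must lie in [-1, 1]")
    } else {
      if (min(object@L) < -1e-9 || max(object@L) > 100 + 1e-6)
        return("L* must lie in [0, 100]")
    }
    TRUE
  })

#' Construct a LabImage
#'
#' @param L,a,b numeric matrices of equal dimension.
#' @param normalized logical; `TRUE` if the planes are in the [-1, 1]
#'   training range.
#' @return A [LabImage-class] object.
#' @export
LabImage <- function(L, a, b, normalized = FALSE) {
  new("LabImage", L = L, a = a, b = b, normalized = isTRUE(normalized))
}

#' @describeIn LabImage-class the Lightness plane.
#' @param x a `LabImage`.
#' @export
labL <- function(x) x@L
#' @describeIn LabImage-class the a* plane.
#' @export
labA <- function(x) x@a
#' @describeIn LabImage-class the b* plane.
#' @export
labB <- function(x) x@b
#' @describeIn LabImage-class whether the planes are in the [-1, 1] range.
#' @export
isNormalized <- function(x) x@normalized

setMethod("show", "LabImage", function(object) {
  d <- dim(object@L)
  cat(sprintf("LabImage %d x %d (%s)\n  L in [%.2f, %.2f]  a in [%.2f, %.2f]  b in [%.2f, %.2f]\n",
              d[1], d[2],
              if (object@normalized) "normalized [-1,1]" else "L* 0-100, a*/b* -128..127",
              min(object@L), max(object@L), min(object@a), max(object@a),
              min(object@b), max(object@b)))
})

#' Similarity metrics for one image pair
#'
#' @slot psnr peak signal-to-noise ratio in dB (`Inf` iff the images are
#'   identical).
#' @slot ssim structural similarity in [-1, 1].
#' @slot wph weighted patch histogram score in [0, 1].
#' @slot wphMap per-patch WPH similarity map (diagnostic).
#' @export
setClass("MetricReport",
  representation(psnr = "numeric", ssim = "numeric", wph = "numeric",
                 wphMap = "matrix"),
  validity = function(object) {
    if (object@wph < -1e-12 || object@wph > 1 + 1e-12)
      return("wph must lie in [0, 1]")
    if (object@ssim < -1 - 1e-9 || object@ssim > 1 + 1e-9)
      return("ssim must lie in [-1, 1]")
    if (object@psnr < 0) return("psnr must be non-negative")
    TRUE
  })

setMethod("show", "MetricReport", function(object) {
  cat(sprintf("MetricReport  PSNR %s dB  SSIM %.4f  WPH %.4f\n",
              if (is.infinite(object@psnr)) "inf" else sprintf("%.2f", object@psnr),
              object@ssim, object@wph))
})

#' @describeIn MetricReport-class PSNR in dB.
#' @param x a `MetricReport`.
#' @export
psnrValue <- function(x) x@psnr
#' @describeIn MetricReport-class SSIM.
#' @export
ssimValue <- function(x) x@ssim
#' @describeIn MetricReport-class WPH score.
#' @export
wphValue <- function(x) x@wph

#' Per-channel fluorescence quantification
#'
#' The five Organalysis-style measurements for one fluorescence channel:
#' organoid area (pixel count above threshold), percentage of the image
#' covered, total fluorescence intensity over the organoid mask, intensity
#' per organoid pixel, and intensity per image pixel.  Ratio measurements
#' are `NA` (an explicit undefined sentinel) when the organoid area is zero.
#'
#' @slot organoidArea pixel count of the fluorescent mask.
#' @slot pctCoverage 100 * area / image area.
#' @slot totalIntensity summed 8-bit counts over the mask.
#' @slot intensityByArea totalIntensity / organoidArea.
#' @slot intensityByImageArea totalIntensity / image pixel count.
#' @slot threshold the 8-bit threshold used (strict `>`).
#' @slot channel channel label ("R", "G" or "B").
#' @export
setClass("ChannelMeasurements",
  representation(organoidArea = "numeric", pctCoverage = "numeric",
                 totalIntensity = "numeric", intensityByArea = "numeric",
                 intensityByImageArea = "numeric", threshold = "numeric",
                 channel = "character"))

setMethod("show", "ChannelMeasurements", function(object) {
  cat(sprintf(
    "ChannelMeasurements [%s, T=%g]\n  area %g px  coverage %.2f%%  total %g  per-area %s  per-image-area %g\n",
    object@channel, object@threshold, object@organoidArea, object@pctCoverage,
    object@totalIntensity,
    if (is.na(object@intensityByArea)) "undefined" else sprintf("%.3f", object@intensityByArea),
    object@intensityByImageArea))
})

#' U-Net generator network
#'
#' Encoder-decoder network with skip connections that maps a normalized
#' Lightness plane (1 x H x W, values in [-1, 1]) to the two chromatic
#' planes a*, b* (2 x H x W, tanh-bounded in [-1, 1]).  Optionally refines
#' skip and bottleneck feature maps with convolutional block attention
#' (CBAM).  Layer parameters live in reference (environment) objects so the
#' optimizer updates them in place.
#'
#' @slot config list of architectural settings (image size, depth, base
#'   channels, CBAM flag, seed).
#' @slot layers list of layer objects.
#' @export
setClass("GeneratorNet", representation(config = "list", layers = "list"))

#' Patch discriminator network
#'
#' Convolutional classifier scoring overlapping local patches of a
#' (condition, a*b*) stack as real or fake; the image-level score is the
#' mean of the patch scores.  With the default layer stack each score has a
#' 70 x 70 pixel receptive field (a 30 x 30 map at 256 x 256).
#'
#' @slot config list of architectural settings.
#' @slot layers list of layer objects.
#' @export
setClass("DiscriminatorNet", representation(config = "list", layers = "list"))

setMethod("show", "GeneratorNet", function(object) {
  cfg <- object@config
  cat(sprintf("GeneratorNet  %dx%d, depth %d, base %d channels, CBAM %s (%d parameters)\n",
              cfg$size, cfg$size, cfg$depth, cfg$base,
              if (isTRUE(cfg$cbam)) "on" else "off", countParams(object)))
})

setMethod("show", "DiscriminatorNet", function(object) {
  cfg <- object@config
  cat(sprintf("DiscriminatorNet  %d input channels, base %d (%d parameters)\n",
              cfg$inChannels, cfg$base, countParams(object)))
})
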