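# sRGB <-> CIELAB conversion chain: inverse gamma, the D65 sRGB-to-XYZ
# matrix, and the CIE f(t) nonlinearity with delta = 6/29.

# 4-decimal D65 sRGB->XYZ matrix; rows sum to the D65 white within rounding
.RGB2XYZ <- matrix(c(0.4124, 0.3576, 0.1805,
                     0.2126, 0.7152, 0.0722,
                     0.0193, 0.1192, 0.9505),
                   nrow = 3, byrow = TRUE)
.XYZ2RGB <- solve(.RGB2XYZ)

# D65 reference white, 2 degree observer
.WHITE <- c(X = 0.95047, Y = 1.00000, Z = 1.08883)

.DELTA <- 6 / 29

# CIE f(t): cube root above delta^3, linear continuation below
.labF <- function(t) {
  ifelse(t > .DELTA^3, t^(1 / 3), t / (3 * .DELTA^2) + 4 / 29)
}

.labFinv <- function(ft) {
  ifelse(ft > .DELTA, ft^3, 3 * .DELTA^2 * (ft - 4 / 29))
}

.srgbDecode <- function(s) {
  ifelse(s <= 0.04045, s / 12.92, ((s + 0.055) / 1.055)^2.4)
}

.srgbEncode <- function(lin) {
  lin <- pmax(lin, 0)
  ifelse(lin <= 0.04045 / 12.92, lin * 12.92, 1.055 * lin^(1 / 2.4) - 0.055)
}

#' Convert an 8-bit RGB image to CIELAB
#'
#' Applies the standard chain: scale to [0, 1], piecewise sRGB inverse gamma,
#' the D65 RGB-to-XYZ matrix, normalization by the D65 white and the CIE
#' piecewise cube-root nonlinearity (delta = 6/29).  a* and b* are returned
#' unclamped; clipping to the 8-bit storage range happens only at
#' normalization or serialization so round trips do not compound error.
#'
#' @param img an [RgbImage-class] (or plain H x W x 3 array in [0, 255]).
#' @return An unnormalized [LabImage-class]; L* in [0, 100], a*/b* around
#'   [-128, 127] (the sRGB gamut stays within about +-108).
#' @export
rgbToLab <- function(img) {
  px <- unclass(img)
  d <- dim(px)
  if (is.null(d) || length(d) != 3L || d[3] != 3L)
    stop("rgbToLab() needs an H x W x 3 image")
  lin <- .srgbDecode(px / 255)
  l1 <- matrix(lin[, , 1], d[1], d[2])
  l2 <- matrix(lin[, , 2], d[1], d[2])
  l3 <- matrix(lin[, , 3], d[1], d[2])
  X <- (.RGB2XYZ[1, 1] * l1 + .RGB2XYZ[1, 2] * l2 + .RGB2XYZ[1, 3] * l3) / .WHITE[1]
  Y <- (.RGB2XYZ[2, 1] * l1 + .RGB2XYZ[2, 2] * l2 + .RGB2XYZ[2, 3] * l3) / .WHITE[2]
  Z <- (.RGB2XYZ[3, 1] * l1 + .RGB2XYZ[3, 2] * l2 + .RGB2XYZ[3, 3] * l3) / .WHITE[3]
  fX <- .labF(X); fY <- .labF(Y); fZ <- .labF(Z)
  LabImage(L = pmin(pmax(116 * fY - 16, 0), 100),
           a = 500 * (fX - fY),
           b = 200 * (fY - fZ),
           normalized = FALSE)
}

#' Convert a CIELAB image back to 8-bit RGB
#'
#' Exact algebraic inverse of [rgbToLab()].  Out-of-gamut values are clipped
#' to [0, 255]; rounding is round-half-even.
#'
#' @param img an unnormalized [LabImage-class].
#' @return An [RgbImage-class].
#' @export
labToRgb <- function(img) {
  if (isNormalized(img))
    stop("labToRgb() expects an unnormalized LabImage; call normalizeLab(img, \"inverse\") first")
  fY <- (img@L + 16) / 116
  fX <- fY + img@a / 500
  fZ <- fY - img@b / 200
  X <- .labFinv(fX) * .WHITE[1]
  Y <- .labFinv(fY) * .WHITE[2]
  Z <- .labFinv(fZ) * .WHITE[3]
  d <- dim(img@L)
  px <- array(0, dim = c(d[1], d[2], 3))
  for (ch in 1:3) {
    lin <- .XYZ2RGB[ch, 1] * X + .XYZ2RGB[ch, 2] * Y + .XYZ2RGB[ch, 3] * Z
    px[, , ch] <- pmin(pmax(round(.srgbEncode(lin) * 255), 0), 255)
  }
  RgbImage(px)
}

#' Normalize CIELAB planes to the [-1, 1] training range (and back)
#'
#' Forward maps L* by L/50 - 1 and a*, b* by clip(v, -128, 127)/128;
#' inverse applies the exact inverse affine maps.  The `normalized` flag on
#' the image records its state, and re-applying a direction is an error.
#'
#' @param img a [LabImage-class].
#' @param direction `"forward"` (to [-1, 1]) or `"inverse"` (back to
#'   L* 0-100, a*/b* -128..127).
#' @return A [LabImage-class] with the flag flipped.
#' @export
normalizeLab <- function(img, direction = c("forward", "inverse")) {
  direction <- match.arg(direction)
  if (direction == "forward") {
    if (isNormalized(img)) stop("LabImage is already normalized")
    LabImage(L = img@L / 50 - 1,
             a = pmin(pmax(img@a, -128), 127) / 128,
             b = pmin(pmax(img@b, -128), 127) / 128,
             normalized = TRUE)
  } else {
    if (!isNormalized(img)) stop("LabImage is not normalized")
    LabImage(L = (img@L + 1) * 50,
             a = img@a * 128,
             b = img@b * 128,
             normalized = FALSE)
  }
}

#' Merge a Lightness plane with generated chromatic planes
#'
#' Utility used at prediction time: the generator outputs only a* and b*;
#' the colorized image is obtained by merging them onto the grayscale
#' (Lightness) input.
#'
#' @param L numeric matrix, unnormalized L* plane in [0, 100].
#' @param a,b numeric matrices, unnormalized a*/b* planes.
#' @return An unnormalized [LabImage-class].
#' @export
mergeLightness <- function(L, a, b) LabImage(L = L, a = a, b = b, normalized = FALSE)
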