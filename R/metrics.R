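# The three evaluation metrics, computed on 8-bit RGB pairs: PSNR, SSIM and
# the weighted patch histogram (WPH), which compares per-patch color
# histograms on a regular grid with the central region of interest
# up-weighted.

.checkPair <- function(I, K) {
  I <- .asRgbArray(I); K <- .asRgbArray(K)
  if (!identical(dim(I), dim(K)))
    stop("images must share dimensions")
  list(I = I, K = K)
}

#' Peak signal-to-noise ratio
#'
#' PSNR = 20*log10(255) - 10*log10(MSE) with MSE the mean squared
#' difference over all pixels and channels; identical images give `Inf`
#' (reported as the string "inf" in CSV reports, never silently capped).
#'
#' @param I,K [RgbImage-class] objects (or H x W x 3 arrays) of equal size.
#' @return PSNR in dB.
#' @export
psnr <- function(I, K) {
  p <- .checkPair(I, K)
  mse <- mean((p$I - p$K)^2)
  if (mse == 0) return(Inf)
  20 * log10(255) - 10 * log10(mse)
}

# 2-D Gaussian filtering of one plane via the package conv kernel ("valid")
.gaussFilter <- function(m, kern, k) {
  x <- array(m, c(1L, nrow(m), ncol(m), 1L))
  y <- cpp_conv_fwd(x, kern, 0, k, 1L, 0L)
  matrix(y[1L, , , 1L], dim(y)[2], dim(y)[3])
}

#' Structural similarity index
#'
#' Windowed product of the luminance, contrast and structure comparison
#' terms with the standard stabilizing constants (K1 = 0.01, K2 = 0.03,
#' dynamic range 255) under an 11 x 11 Gaussian window (sigma 1.5), averaged
#' over all valid windows and the three RGB channels.  Result lies in
#' [-1, 1]; identical images give exactly 1.
#'
#' @param x,y [RgbImage-class] objects (or H x W x 3 arrays) of equal size,
#'   at least 11 pixels on each side.
#' @param windowSize odd window side (default 11).
#' @param sigma Gaussian window standard deviation (default 1.5).
#' @return scalar SSIM.
#' @export
ssim <- function(x, y, windowSize = 11L, sigma = 1.5) {
  p <- .checkPair(x, y)
  d <- dim(p$I)
  if (d[1] < windowSize || d[2] < windowSize)
    stop("image smaller than the SSIM window")
  off <- seq_len(windowSize) - (windowSize + 1) / 2
  g <- exp(-off^2 / (2 * sigma^2))
  w <- outer(g, g); w <- w / sum(w)
  kern <- matrix(as.numeric(w), 1L)       # row order matches im2col layout
  C1 <- (0.01 * 255)^2
  C2 <- (0.03 * 255)^2
  vals <- vapply(1:3, function(ch) {
    a <- p$I[, , ch]; b <- p$K[, , ch]
    mux <- .gaussFilter(a, kern, windowSize)
    muy <- .gaussFilter(b, kern, windowSize)
    sxx <- .gaussFilter(a * a, kern, windowSize) - mux^2
    syy <- .gaussFilter(b * b, kern, windowSize) - muy^2
    sxy <- .gaussFilter(a * b, kern, windowSize) - mux * muy
    m <- ((2 * mux * muy + C1) * (2 * sxy + C2)) /
         ((mux^2 + muy^2 + C1) * (sxx + syy + C2))
    mean(m)
  }, numeric(1))
  mean(vals)
}

#' WPH configuration
#'
#' @param patchSize patch side in pixels (must divide both image sides).
#' @param bins histogram bins per channel over [0, 255].
#' @param roi optional logical matrix over the patch grid marking the region
#'   of interest; `NULL` selects the default centered block covering half the
#'   grid in each direction (the organoid-centered ROI).
#' @param roiWeight weight multiplier (>= 1) for ROI patches; 1.5 implements
#'   the published 50% up-weighting.
#' @param kernel histogram comparison function: `"intersection"` (sum of
#'   bin-wise minima of the probability histograms; symmetric, in [0, 1],
#'   exactly 1 for identical patches) or `"correlation"` (Pearson correlation
#'   clamped to [0, 1]).
#' @return list of class `"wphConfig"`.
#' @export
wphConfig <- function(patchSize = 32L, bins = 32L, roi = NULL,
                      roiWeight = 1.5,
                      kernel = c("intersection", "correlation")) {
  if (bins < 2L) stop("need at least 2 bins")
  if (roiWeight < 1) stop("roiWeight must be >= 1")
  structure(list(patchSize = as.integer(patchSize), bins = as.integer(bins),
                 roi = roi, roiWeight = roiWeight,
                 kernel = match.arg(kernel)),
            class = "wphConfig")
}

.defaultRoi <- function(gh, gw) {
  roi <- matrix(FALSE, gh, gw)
  lh <- max(1L, gh %/% 2L); lw <- max(1L, gw %/% 2L)
  rs <- (gh - lh) %/% 2L; cs <- (gw - lw) %/% 2L
  roi[rs + seq_len(lh), cs + seq_len(lw)] <- TRUE
  roi
}

.patchHist <- function(v, bins) {
  idx <- pmin(floor(v * bins / 256), bins - 1L) + 1L
  tabulate(idx, nbins = bins) / length(v)
}

.histSim <- function(h1, h2, kernel) {
  if (kernel == "intersection") return(sum(pmin(h1, h2)))
  if (stats::sd(h1) == 0 || stats::sd(h2) == 0)
    return(as.numeric(all(h1 == h2)))
  max(0, stats::cor(h1, h2))
}

#' Weighted patch histogram similarity
#'
#' Partitions both images into a regular grid of `patchSize` x `patchSize`
#' patches, builds a `bins`-bin probability histogram per patch and RGB
#' channel, compares corresponding histograms with the configured kernel
#' (channel-averaged, in [0, 1]) and returns the ROI-weighted mean:
#' score = sum(w_p * s_p) / sum(w_p) with w_p = `roiWeight` inside the ROI
#' and 1 outside.  Identical images score exactly 1.
#'
#' @param I,K [RgbImage-class] objects (or H x W x 3 arrays) of equal size.
#' @param cfg a [wphConfig()].
#' @return list with `score` and the per-patch similarity `map`.
#' @export
wph <- function(I, K, cfg = wphConfig()) {
  p <- .checkPair(I, K)
  d <- dim(p$I)
  ps <- cfg$patchSize
  if (d[1] %% ps != 0 || d[2] %% ps != 0)
    stop("patch size ", ps, " does not divide the image dimensions")
  gh <- d[1] %/% ps; gw <- d[2] %/% ps
  roi <- cfg$roi %||% .defaultRoi(gh, gw)
  if (!identical(dim(roi), c(gh, gw)))
    stop("roi mask must match the ", gh, " x ", gw, " patch grid")
  map <- matrix(0, gh, gw)
  for (gi in seq_len(gh)) {
    rows <- (gi - 1L) * ps + seq_len(ps)
    for (gj in seq_len(gw)) {
      cols <- (gj - 1L) * ps + seq_len(ps)
      s <- 0
      for (ch in 1:3) {
        h1 <- .patchHist(as.vector(p$I[rows, cols, ch]), cfg$bins)
        h2 <- .patchHist(as.vector(p$K[rows, cols, ch]), cfg$bins)
        s <- s + .histSim(h1, h2, cfg$kernel)
      }
      map[gi, gj] <- s / 3
    }
  }
  w <- matrix(1, gh, gw)
  w[roi] <- cfg$roiWeight
  list(score = sum(w * map) / sum(w), map = map)
}

#' Compute all three metrics for one image pair
#'
#' @param I generated image, `K` ground truth ([RgbImage-class] or array).
#' @param K ground truth image.
#' @param cfg a [wphConfig()].
#' @return A [MetricReport-class].
#' @export
evaluatePair <- function(I, K, cfg = wphConfig()) {
  wr <- wph(I, K, cfg)
  new("MetricReport", psnr = psnr(I, K), ssim = ssim(I, K),
      wph = wr$score, wphMap = wr$map)
}
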