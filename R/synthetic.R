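# Procedural generator of paired phase-contrast / fluorescence organoid
# images.  Emulates ring-shaped micropatterned cardiac organoids: a broad
# cardiomyocyte (CM, green/GFP) domain on the ring body and a sparser
# branching endothelial-cell (EC, red/mOrange) network, with phase-contrast
# texture statistics tied to cell identity so that colorization is learnable
# from the grayscale image alone.  Ground-truth binary masks are returned as
# oracle labels.

#' Synthetic organoid configuration
#'
#' @param size image side in pixels (power of two for network use).
#' @param outerRadius,innerRadius ring radii as fractions of the half-image
#'   (in (0, 1), inner < outer); the outer circle mimics the 2000 um
#'   micropattern footprint.
#' @param cmFill fraction of the ring body occupied by the CM domain.
#' @param ecDensity EC network density in [0, 1] (scales the number of
#'   branching walkers).
#' @param cmGrain,ecGrain phase-texture grain size (Gaussian smoothing
#'   sigma, px) of the CM and EC regions.
#' @param cmContrast,ecContrast phase-texture contrast (8-bit counts).
#' @param bgLevel mean phase background brightness (bright field).
#' @param noiseSd sd of the global white noise added to the phase image.
#' @param shiftBrightness,shiftGrainScale domain-shift knobs applied when a
#'   pair is generated with `newBatch = TRUE`: a global phase brightness
#'   offset and a texture-scale factor emulating a new differentiation
#'   batch.
#' @param seed base seed; `generatePair()` adds its `index` argument.
#' @return list of class `"syntheticConfig"`.
#' @export
syntheticConfig <- function(size = 64L, outerRadius = 0.9, innerRadius = 0.4,
                            cmFill = 0.85, ecDensity = 0.5, cmGrain = 3,
                            ecGrain = 1, cmContrast = 25, ecContrast = 45,
                            bgLevel = 200, noiseSd = 4,
                            shiftBrightness = 30, shiftGrainScale = 1.8,
                            seed = 1L) {
  if (outerRadius <= 0 || outerRadius >= 1 || innerRadius <= 0 ||
      innerRadius >= outerRadius)
    stop("need 0 < innerRadius < outerRadius < 1")
  if (cmFill <= 0 || cmFill > 1 || ecDensity < 0 || ecDensity > 1)
    stop("cmFill must lie in (0, 1], ecDensity in [0, 1]")
  structure(list(size = as.integer(size), outerRadius = outerRadius,
                 innerRadius = innerRadius, cmFill = cmFill,
                 ecDensity = ecDensity, cmGrain = cmGrain, ecGrain = ecGrain,
                 cmContrast = cmContrast, ecContrast = ecContrast,
                 bgLevel = bgLevel, noiseSd = noiseSd,
                 shiftBrightness = shiftBrightness,
                 shiftGrainScale = shiftGrainScale,
                 seed = as.integer(seed)),
            class = "syntheticConfig")
}

# Gaussian-smoothed white-noise field, standardized to unit sd
.noiseField <- function(H, W, sigma) {
  z <- matrix(stats::rnorm(H * W), H, W)
  if (sigma > 0) {
    k <- 2L * as.integer(ceiling(2 * sigma)) + 1L
    off <- seq_len(k) - (k + 1) / 2
    g <- exp(-off^2 / (2 * sigma^2)); g <- g / sum(g)
    kern <- matrix(as.numeric(outer(g, g)), 1L)
    x <- array(z, c(1L, H, W, 1L))
    y <- cpp_conv_fwd(x, kern, 0, k, 1L, (k - 1L) %/% 2L)
    z <- matrix(y[1L, , , 1L], H, W)
  }
  (z - mean(z)) / stats::sd(z)
}

# branching random-walk vessel network confined to the organoid body
.ecNetwork <- function(size, rNorm, inner, outer, density) {
  mask <- matrix(FALSE, size, size)
  nWalk <- max(1L, round(8 * density))
  half <- size / 2
  c0 <- (size + 1) / 2
  walkers <- lapply(seq_len(nWalk), function(i) {
    th <- stats::runif(1, 0, 2 * pi)
    r0 <- half * (inner + outer) / 2
    list(x = c0 + r0 * cos(th), y = c0 + r0 * sin(th),
         dir = stats::runif(1, 0, 2 * pi), life = round(size * 1.5))
  })
  maxWalk <- nWalk * 6L
  while (length(walkers) > 0) {
    w <- walkers[[1]]; walkers <- walkers[-1]
    while (w$life > 0) {
      w$life <- w$life - 1
      w$dir <- w$dir + stats::rnorm(1, 0, 0.35)
      w$x <- w$x + cos(w$dir); w$y <- w$y + sin(w$dir)
      i <- round(w$x); j <- round(w$y)
      if (i < 1 || i > size || j < 1 || j > size) break
      if (rNorm[i, j] > outer || rNorm[i, j] < inner * 0.7) break
      mask[i, j] <- TRUE
      if (stats::runif(1) < 0.03 && maxWalk > 0) {
        maxWalk <- maxWalk - 1L
        walkers[[length(walkers) + 1L]] <-
          list(x = w$x, y = w$y, dir = w$dir + sample(c(-1, 1), 1) * pi / 3,
               life = round(w$life * 0.7))
      }
    }
  }
  # dilate by one pixel so vessels are 2-3 px wide
  d <- mask
  d[-1, ] <- d[-1, ] | mask[-nrow(mask), ]
  d[-nrow(d), ] <- d[-nrow(d), ] | mask[-1, ]
  d[, -1] <- d[, -1] | mask[, -ncol(mask)]
  d[, -ncol(d)] <- d[, -ncol(d)] | mask[, -1]
  d
}

#' Generate one paired synthetic sample
#'
#' Fluorescence image: green (GFP-CM) intensity on the CM ring body, red
#' (mOrange-EC) intensity on a branching vessel network inside it, black
#' background (exactly 0 outside the masks).  Phase image: bright-field-like
#' grayscale where CM and EC regions carry distinct grain size, brightness
#' and contrast plus global noise.  Identical `cfg`, `index` and `newBatch`
#' reproduce the pair bitwise.
#'
#' @param cfg a [syntheticConfig()].
#' @param index sample index; the pair is generated under seed
#'   `cfg$seed + index`.
#' @param newBatch apply the domain-shift knobs (brightness offset, texture
#'   rescale) emulating a new differentiation batch.
#' @return list with `phase` and `fluor` ([RgbImage-class]) plus the binary
#'   oracle masks `cmMask` and `ecMask`.
#' @export
generatePair <- function(cfg = syntheticConfig(), index = 0L,
                         newBatch = FALSE) {
  if (!inherits(cfg, "syntheticConfig")) stop("cfg must be a syntheticConfig")
  S <- cfg$size
  cmGrain <- if (newBatch) cfg$cmGrain * cfg$shiftGrainScale else cfg$cmGrain
  bright <- if (newBatch) cfg$shiftBrightness else 0
  .withSeed(cfg$seed + as.integer(index), {
    c0 <- (S + 1) / 2
    rc <- (seq_len(S) - c0) / (S / 2)
    rNorm <- sqrt(outer(rc^2, rc^2, "+"))
    ring <- rNorm <= cfg$outerRadius & rNorm >= cfg$innerRadius
    if (!any(ring)) stop("degenerate ring geometry")
    fCM <- .noiseField(S, S, cmGrain)
    cm <- ring & fCM > stats::quantile(fCM[ring], 1 - cfg$cmFill)
    ec <- .ecNetwork(S, rNorm, cfg$innerRadius, cfg$outerRadius, cfg$ecDensity)
    # fluorescence: intensity modulated inside the masks, 0 elsewhere
    modG <- .noiseField(S, S, 2)
    fluor <- array(0, c(S, S, 3))
    g <- pmin(pmax(180 + 30 * modG, 60), 255)
    r <- pmin(pmax(200 + 25 * modG, 80), 255)
    fluor[, , 2][cm] <- round(g[cm])
    fluor[, , 1][ec] <- round(r[ec])
    # phase contrast: texture statistics follow cell identity
    tCM <- .noiseField(S, S, cmGrain)
    tEC <- .noiseField(S, S, cfg$ecGrain)
    tBody <- .noiseField(S, S, 2)
    phase <- matrix(cfg$bgLevel, S, S) + 6 * .noiseField(S, S, 1)
    body <- rNorm <= cfg$outerRadius
    phase[body] <- 160 + 12 * tBody[body]
    phase[cm] <- 120 + cfg$cmContrast * tCM[cm]
    phase[ec] <- 70 + cfg$ecContrast * tEC[ec]
    phase <- phase + bright + cfg$noiseSd * matrix(stats::rnorm(S * S), S, S)
    phase <- pmin(pmax(round(phase), 0), 255)
    ph <- array(phase, c(S, S, 3))
    list(phase = RgbImage(ph), fluor = RgbImage(fluor),
         cmMask = cm, ecMask = ec)
  })
}

#' Generate a paired dataset on disk
#'
#' Writes `n` synthetic pairs as PNG files plus a manifest CSV with columns
#' `id`, `phase_path`, `fluor_path`, `split` and `batch_tag`.  The default
#' split ratio mirrors a ~95/5 train/test allocation.  With
#' `shiftForTestBatch = TRUE` the test rows are generated with the
#' domain-shift knobs and tagged `"new_batch"`, exercising the fine-tuning
#' scenario.
#'
#' @param n number of pairs (>= 2; at least one lands in each split).
#' @param dir output directory (created if needed).
#' @param cfg a [syntheticConfig()].
#' @param splitRatio fraction of pairs assigned to the training split.
#' @param shiftForTestBatch logical, see above.
#' @return the manifest data.frame (also written to `dir/manifest.csv`).
#' @export
generateDataset <- function(n, dir, cfg = syntheticConfig(),
                            splitRatio = 1374 / 1453,
                            shiftForTestBatch = FALSE) {
  if (n < 2L) stop("need at least 2 pairs")
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create output directory ", dir)
  nTrain <- min(max(round(splitRatio * n), 1L), n - 1L)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    isTest <- i > nTrain
    shifted <- isTest && shiftForTestBatch
    pair <- generatePair(cfg, index = i, newBatch = shifted)
    id <- sprintf("co%04d", i)
    pp <- file.path(dir, paste0(id, "_phase.png"))
    fp <- file.path(dir, paste0(id, "_fluor.png"))
    writeRgbPng(pair$phase, pp)
    writeRgbPng(pair$fluor, fp)
    rows[[i]] <- data.frame(id = id, phase_path = pp, fluor_path = fp,
                            split = if (isTest) "test" else "train",
                            batch_tag = if (shifted) "new_batch" else "base")
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}
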