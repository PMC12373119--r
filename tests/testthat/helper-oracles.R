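# Deterministic fixtures and independent oracles used across the suite.

# arithmetic test pattern: pixel (i, j, c) = (ai*i + aj*j + ac*c + o) mod 256
patternImage <- function(size = 64, ai = 7, aj = 13, ac = 31, o = 0) {
  a <- array(0, c(size, size, 3))
  for (ch in 1:3)
    a[, , ch] <- outer(0:(size - 1), 0:(size - 1),
                       function(i, j) (ai * i + aj * j + ac * (ch - 1) + o) %% 256)
  RgbImage(a)
}

randomImage <- function(size = 64, seed = 1) {
  set.seed(seed)
  RgbImage(array(sample(0:255, size * size * 3, replace = TRUE),
                 c(size, size, 3)))
}

# brute-force weighted patch histogram, written independently of wph():
# explicit loops, histogram by counting with sum(), intersection by min()
bruteWph <- function(I, K, patchSize = 32, bins = 32, roiWeight = 1.5,
                     roi = NULL) {
  I <- unclass(I); K <- unclass(K)
  gh <- nrow(I) / patchSize; gw <- ncol(I) / patchSize
  if (is.null(roi)) {
    roi <- matrix(FALSE, gh, gw)
    lh <- max(1, gh %/% 2); lw <- max(1, gw %/% 2)
    roi[(gh - lh) %/% 2 + seq_len(lh), (gw - lw) %/% 2 + seq_len(lw)] <- TRUE
  }
  num <- 0; den <- 0
  width <- 256 / bins
  for (gi in 1:gh) for (gj in 1:gw) {
    sim <- 0
    for (ch in 1:3) {
      p1 <- I[(gi - 1) * patchSize + 1:patchSize,
              (gj - 1) * patchSize + 1:patchSize, ch]
      p2 <- K[(gi - 1) * patchSize + 1:patchSize,
              (gj - 1) * patchSize + 1:patchSize, ch]
      inter <- 0
      for (b in 1:bins) {
        lo <- (b - 1) * width; hi <- b * width
        c1 <- sum(p1 >= lo & (p1 < hi | (b == bins & p1 <= 255)))
        c2 <- sum(p2 >= lo & (p2 < hi | (b == bins & p2 <= 255)))
        inter <- inter + min(c1, c2)
      }
      sim <- sim + inter / length(p1)
    }
    w <- if (roi[gi, gj]) roiWeight else 1
    num <- num + w * sim / 3
    den <- den + w
  }
  num / den
}

# central-difference gradient check: fwdloss(backward) must return the
# scalar loss and, when backward = TRUE, populate the cells' gradients
gradCheckCells <- function(fwdloss, cells, nPerCell = 3, eps = 1e-5) {
  organoColor:::.zeroGrads(cells)
  fwdloss(backward = TRUE)
  worst <- 0
  for (p in cells) {
    for (i in sample(length(p$p), min(nPerCell, length(p$p)))) {
      o <- p$p[i]
      p$p[i] <- o + eps; lp <- fwdloss(backward = FALSE)
      p$p[i] <- o - eps; lm <- fwdloss(backward = FALSE)
      p$p[i] <- o
      num <- (lp - lm) / (2 * eps)
      worst <- max(worst, abs(num - p$g[i]) / max(1e-6, abs(num) + abs(p$g[i])))
    }
  }
  worst
}

# small in-memory paired dataset for training tests
tinyPairs <- function(n, size = 32, seed = 50, newBatch = FALSE) {
  cfg <- syntheticConfig(size = size, seed = seed)
  lapply(seq_len(n), function(i)
    generatePair(cfg, index = i, newBatch = newBatch)[c("phase", "fluor")])
}

meanMetrics <- function(gen, pairs, cfg = wphConfig()) {
  m <- vapply(pairs, function(p) {
    pred <- predictColors(gen, p$phase)
    r <- evaluatePair(pred, p$fluor, cfg)
    c(psnr = psnrValue(r), ssim = ssimValue(r), wph = wphValue(r))
  }, numeric(3))
  rowMeans(m)
}
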