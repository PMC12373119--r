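# PSNR / SSIM / WPH identities, closed forms and oracle equivalence.

test_that("psnr closed forms: identity, one-count offset, full-range error", {
  I <- patternImage(32)
  expect_identical(psnr(I, I), Inf)
  I0 <- RgbImage(array(100, c(16, 16, 3)))
  K1 <- RgbImage(array(101, c(16, 16, 3)))
  expect_equal(psnr(I0, K1), 20 * log10(255), tolerance = 1e-12)
  black <- RgbImage(array(0, c(16, 16, 3)))
  white <- RgbImage(array(255, c(16, 16, 3)))
  expect_equal(psnr(black, white), 0, tolerance = 1e-12)
  expect_error(psnr(I, I0), "share dimensions")
})

test_that("ssim equals 1 on identity and the luminance closed form on constants", {
  I <- patternImage(32)
  expect_equal(ssim(I, I), 1, tolerance = 1e-12)
  A <- RgbImage(array(100, c(16, 16, 3)))
  B <- RgbImage(array(110, c(16, 16, 3)))
  C1 <- (0.01 * 255)^2
  # contrast and structure terms are degenerate (= 1) for constant images
  expect_equal(ssim(A, B),
               (2 * 100 * 110 + C1) / (100^2 + 110^2 + C1),
               tolerance = 1e-9)
  expect_error(ssim(RgbImage(array(0, c(8, 8, 3))),
                    RgbImage(array(0, c(8, 8, 3)))), "window")
})

test_that("ssim is negative for an anti-correlated zero-mean-contrast pattern", {
  set.seed(21)
  base <- array(sample(c(96, 160), 32 * 32 * 3, replace = TRUE), c(32, 32, 3))
  x <- RgbImage(base)
  y <- RgbImage(255 - base)
  expect_lt(ssim(x, y), 0)
})

test_that("psnr and ssim agree with an independent reference implementation", {
  # frozen from scikit-image (data_range 255, gaussian 11x11 sigma 1.5
  # windows, channel-averaged) on the arithmetic 64 px pattern pair
  I <- patternImage(64, 7, 13, 31, 0)
  K <- patternImage(64, 5, 11, 17, 8)
  expect_equal(psnr(I, K), 6.820099891123737, tolerance = 1e-6)
  expect_equal(ssim(I, K), 0.1367865256352614, tolerance = 1e-4)
})

test_that("wph identities: self-similarity 1, disjoint histograms 0, symmetry", {
  I <- randomImage(64, seed = 31)
  expect_equal(wph(I, I)$score, 1)
  black <- RgbImage(array(0, c(64, 64, 3)))
  white <- RgbImage(array(255, c(64, 64, 3)))
  expect_equal(wph(black, white)$score, 0)
  K <- randomImage(64, seed = 32)
  expect_equal(wph(I, K)$score, wph(K, I)$score, tolerance = 1e-15)
  expect_error(wph(I, K, wphConfig(patchSize = 24)), "does not divide")
})

test_that("wph ignores within-patch pixel position", {
  I <- randomImage(64, seed = 33)
  px <- unclass(I)
  set.seed(34)
  perm <- sample(32 * 32)
  shuffled <- px
  for (gi in 0:1) for (gj in 0:1) for (ch in 1:3) {
    patch <- px[gi * 32 + 1:32, gj * 32 + 1:32, ch]
    shuffled[gi * 32 + 1:32, gj * 32 + 1:32, ch] <- matrix(patch[perm], 32)
  }
  K <- RgbImage(shuffled)
  expect_equal(wph(I, K)$score, 1)
})

test_that("wph equals the brute-force oracle and the unweighted mean at w=1", {
  I <- randomImage(64, seed = 35)
  K <- randomImage(64, seed = 36)
  expect_equal(wph(I, K)$score, bruteWph(I, K), tolerance = 1e-12)
  I2 <- patternImage(128, 3, 5, 7)
  K2 <- randomImage(128, seed = 37)
  expect_equal(wph(I2, K2)$score, bruteWph(I2, K2), tolerance = 1e-12)
  r <- wph(I, K, wphConfig(roiWeight = 1))
  expect_equal(r$score, mean(r$map), tolerance = 1e-12)
})

test_that("roi up-weighting moves the score toward the central patches", {
  set.seed(38)
  px <- array(sample(0:255, 64 * 64 * 3, TRUE), c(64, 64, 3))
  I <- RgbImage(px)
  center <- px
  center[17:48, 17:48, ] <- pmin(center[17:48, 17:48, ] + 40, 255)
  K <- RgbImage(center)  # degraded only inside the default ROI
  w1 <- wph(I, K, wphConfig(patchSize = 8, roiWeight = 1))$score
  w15 <- wph(I, K, wphConfig(patchSize = 8, roiWeight = 1.5))$score
  expect_lt(w15, w1)
})

test_that("evaluatePair bundles the three metrics consistently", {
  I <- randomImage(64, seed = 39)
  r <- evaluatePair(I, I)
  expect_identical(psnrValue(r), Inf)
  expect_equal(ssimValue(r), 1, tolerance = 1e-12)
  expect_equal(wphValue(r), 1)
  K <- randomImage(64, seed = 40)
  r2 <- evaluatePair(I, K)
  expect_equal(psnrValue(r2), psnr(I, K))
  expect_equal(wphValue(r2), wph(I, K)$score)
})
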