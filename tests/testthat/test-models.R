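# CBAM contract, network geometry, determinism and analytic gradients.

test_that("CBAM with zero attention parameters scales the input by 0.25", {
  set.seed(1)
  F <- array(rnorm(8 * 16 * 16), c(8, 16, 16))
  blk <- cbamLayer(8, reduction = 8, init = "zero")
  out <- cbamRefine(F, blk)
  expect_equal(out$refined, 0.25 * F)
  expect_equal(dim(out$Mc), c(8L, 1L, 1L))
  expect_equal(dim(out$Ms), c(1L, 16L, 16L))
})

test_that("CBAM preserves geometry, bounds its maps and kills a zero input", {
  set.seed(2)
  F <- array(rnorm(16 * 8 * 8), c(16, 8, 8))
  blk <- cbamLayer(16, reduction = 4)
  out <- cbamRefine(F, blk)
  expect_equal(dim(out$refined), dim(F))
  expect_true(all(out$Mc > 0 & out$Mc < 1))
  expect_true(all(out$Ms > 0 & out$Ms < 1))
  zero <- cbamRefine(array(0, dim(F)), blk)
  expect_equal(zero$refined, array(0, dim(F)))
  expect_error(cbamLayer(10, reduction = 4), "incompatible")
})

test_that("generator maps 1xHxW to a bounded 2xHxW deterministically", {
  for (size in c(64L, 256L)) {
    gen <- buildGenerator(size, base = if (size == 256L) 4L else 8L, seed = 5)
    set.seed(9)
    L <- matrix(runif(size * size, -1, 1), size)
    y1 <- generatorForward(gen, L)
    y2 <- generatorForward(gen, L)
    expect_identical(y1, y2)
    expect_equal(dim(y1), c(2L, size, size))
    expect_true(all(abs(y1) < 1))
  }
  gen <- buildGenerator(64, base = 8, seed = 5)
  expect_error(generatorForward(gen, matrix(0, 48, 48)), "power-of-two")
  expect_error(generatorForward(gen, matrix(0, 32, 32)), "built for")
  expect_error(generatorForward(gen, matrix(2, 64, 64)), "normalized")
  expect_error(buildGenerator(48), "power of two")
})

test_that("patch discriminator yields the printed score-map geometry", {
  d <- buildDiscriminator(3, base = 4, seed = 1)
  set.seed(4)
  ab <- array(runif(2 * 256 * 256, -1, 1), c(2, 256, 256))
  cond <- matrix(runif(256 * 256, -1, 1), 256)
  s <- discriminatorForward(d, cond, ab)
  expect_equal(dim(s$patchScores), c(30L, 30L))
  expect_true(all(s$patchScores > 0 & s$patchScores < 1))
  expect_equal(s$meanScore, mean(s$patchScores), tolerance = 1e-12)
  s2 <- discriminatorForward(d, cond, ab)
  expect_identical(s$patchScores, s2$patchScores)
  expect_error(discriminatorForward(d, matrix(0, 128, 128), ab), "misaligned")
})

test_that("ab-only discriminator variant accepts two channels", {
  d <- buildDiscriminator(2, base = 4, seed = 3)
  set.seed(8)
  ab <- array(runif(2 * 64 * 64, -1, 1), c(2, 64, 64))
  s <- discriminatorForward(d, NULL, ab)
  expect_equal(dim(s$patchScores), c(6L, 6L))
})

test_that("backward passes match central-difference gradients", {
  set.seed(42)
  gen <- buildGenerator(16, base = 4, seed = 7)
  x <- array(runif(1 * 16 * 16 * 2, -1, 1), c(1, 16, 16, 2))
  tgt <- array(runif(2 * 16 * 16 * 2, -1, 1), c(2, 16, 16, 2))
  fG <- function(backward) {
    y <- organoColor:::.genForward(gen, x)
    if (backward) organoColor:::.genBackward(gen, 2 * (y - tgt) / length(y))
    mean((y - tgt)^2)
  }
  expect_lt(gradCheckCells(fG, organoColor:::.netParamCells(gen)), 1e-4)

  d <- buildDiscriminator(3, base = 4, seed = 2)
  xin <- array(runif(3 * 32 * 32 * 2, -1, 1), c(3, 32, 32, 2))
  fD <- function(backward) {
    z <- organoColor:::.discForwardLogits(d, xin)
    b <- organoColor:::.bceWithLogits(z, 1)
    if (backward) organoColor:::.discBackward(d, b$grad)
    b$loss
  }
  expect_lt(gradCheckCells(fD, organoColor:::.netParamCells(d)), 1e-4)
})

test_that("discriminator input gradient (the generator's feedback) is exact", {
  set.seed(13)
  d <- buildDiscriminator(3, base = 4, seed = 2)
  xin <- array(runif(3 * 32 * 32, -1, 1), c(3, 32, 32, 1))
  loss <- function() {
    z <- organoColor:::.discForwardLogits(d, xin)
    organoColor:::.bceWithLogits(z, 1)$loss
  }
  organoColor:::.zeroGrads(organoColor:::.netParamCells(d))
  z <- organoColor:::.discForwardLogits(d, xin)
  b <- organoColor:::.bceWithLogits(z, 1)
  dxin <- organoColor:::.discBackward(d, b$grad)
  eps <- 1e-5
  for (i in sample(length(xin), 6)) {
    o <- xin[i]
    xin[i] <- o + eps; lp <- loss()
    xin[i] <- o - eps; lm <- loss()
    xin[i] <- o
    num <- (lp - lm) / (2 * eps)
    expect_equal(dxin[i], num, tolerance = 1e-4)
  }
})
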