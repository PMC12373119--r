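# Loss closed forms and the adversarial training loop.

test_that("discriminator loss closed forms from the batch cross-entropy", {
  expect_equal(discriminatorLoss(1, 0), 0)
  expect_equal(discriminatorLoss(0.5, 0.5), 2 * log(2), tolerance = 1e-12)
  # duplicating the batch leaves the mean unchanged
  expect_equal(discriminatorLoss(c(0.8, 0.8), c(0.3, 0.3)),
               discriminatorLoss(0.8, 0.3), tolerance = 1e-12)
  # stable logit form agrees with the probability form
  z <- c(-2, 0.5, 3)
  p <- 1 / (1 + exp(-z))
  expect_equal(discriminatorLoss(z, -z, logits = TRUE),
               discriminatorLoss(p, 1 / (1 + exp(z))), tolerance = 1e-12)
  expect_error(discriminatorLoss(numeric(0), numeric(0)), "empty")
})

test_that("generator loss components evaluate to their closed forms", {
  g <- array(runif(32, -1, 1), c(2, 4, 4))
  r <- generatorLoss(1, g, g)
  expect_equal(r$adversarial, 0)
  expect_equal(r$l1, 0)
  expect_equal(r$total, 0)
  r2 <- generatorLoss(0.5, g + 0.1, g, lambda = 100)
  expect_equal(r2$l1, 0.1, tolerance = 1e-12)
  expect_equal(r2$adversarial, log(2), tolerance = 1e-12)
  expect_equal(r2$total, log(2) + 10, tolerance = 1e-10)
  expect_error(generatorLoss(0.5, g, g, lambda = -1), "non-negative")
  expect_error(generatorLoss(0.5, g, array(0, c(2, 2, 2))), "misaligned")
})

test_that("stable logit losses stay finite for extreme logits", {
  z <- c(-1e4, 0, 1e4)
  expect_true(is.finite(discriminatorLoss(z, z, logits = TRUE)))
  g <- array(0, c(2, 2, 2))
  expect_true(is.finite(generatorLoss(z, g, g, logits = TRUE)$total))
})

test_that("training runs, logs every step and is seed-reproducible", {
  pairs <- tinyPairs(8, size = 32)
  tc <- trainingConfig(epochs = 2, batchSize = 4, modelVariant = 2,
                       baseG = 4, baseD = 4, seed = 77)
  ck1 <- trainColorizer(pairs, tc)
  ck2 <- trainColorizer(pairs, tc)
  expect_identical(ck1$history, ck2$history)
  expect_identical(ck1$generatorParams, ck2$generatorParams)
  expect_equal(nrow(ck1$history), 2 * 2)   # 2 epochs x 2 batches
  expect_equal(unname(ck1$counts["d"]), 4)
  expect_true(all(is.finite(unlist(ck1$history[c("lossD", "lossAdv", "lossL1")]))))
})

test_that("model variant 3 performs exactly twice the generator updates", {
  pairs <- tinyPairs(8, size = 32)
  ck2 <- trainColorizer(pairs, trainingConfig(epochs = 2, batchSize = 4,
                                              modelVariant = 2, baseG = 4,
                                              baseD = 4, seed = 5))
  ck3 <- trainColorizer(pairs, trainingConfig(epochs = 2, batchSize = 4,
                                              modelVariant = 3, baseG = 4,
                                              baseD = 4, seed = 5))
  expect_equal(unname(ck3$counts["g"]), 2 * unname(ck2$counts["g"]))
  expect_equal(unname(ck3$counts["d"]), unname(ck2$counts["d"]))
})

test_that("the reconstruction term shrinks over a short smoke run", {
  pairs <- tinyPairs(16, size = 32)
  tc <- trainingConfig(epochs = 6, batchSize = 4, modelVariant = 2,
                       baseG = 8, baseD = 8, seed = 9)
  ck <- trainColorizer(pairs, tc)
  h <- ck$history
  expect_lt(mean(h$lossL1[h$epoch == max(h$epoch)]),
            mean(h$lossL1[h$epoch == 1]))
})

test_that("dataset validation rejects inconsistent geometries", {
  p1 <- tinyPairs(2, size = 32)
  p2 <- tinyPairs(1, size = 16)
  expect_error(trainColorizer(c(p1, p2), trainingConfig(epochs = 1)),
               "inconsistent")
  expect_error(trainColorizer(list(), trainingConfig(epochs = 1)),
               "at least one")
})

test_that("fine-tuning draws exactly floor(fraction * n) new-batch images", {
  pairs <- tinyPairs(6, size = 32)
  newPairs <- tinyPairs(30, size = 32, seed = 60, newBatch = TRUE)
  tc <- trainingConfig(epochs = 1, batchSize = 4, modelVariant = 2,
                       baseG = 4, baseD = 4, seed = 3)
  ck <- trainColorizer(pairs, tc)
  ft <- fineTune(ck, newPairs, pairs, fraction = 1 / 3, epochs = 1)
  expect_length(ft$fineTuneIdx, 10)
  expect_true(all(ft$fineTuneIdx %in% seq_len(30)))
  expect_gt(unname(ft$counts["g"]), unname(ck$counts["g"]))
  expect_error(fineTune(ck, newPairs, pairs, fraction = 0), "fraction")
  expect_error(fineTune(ck, newPairs, pairs, fraction = 1.2), "fraction")
  # fraction 1 degenerates to continued training on everything
  ft1 <- fineTune(ck, newPairs[1:3], pairs, fraction = 1, epochs = 1)
  expect_length(ft1$fineTuneIdx, 3)
})

test_that("checkpoints round-trip through disk and restore the generator", {
  pairs <- tinyPairs(4, size = 32)
  tc <- trainingConfig(epochs = 1, batchSize = 4, modelVariant = 1,
                       baseG = 4, baseD = 4, seed = 12)
  ck <- trainColorizer(pairs, tc)
  path <- tempfile(fileext = ".rds")
  saveCheckpoint(ck, path)
  ck2 <- loadCheckpoint(path)
  expect_identical(ck2$generatorParams, ck$generatorParams)
  g1 <- restoreGenerator(ck)
  g2 <- restoreGenerator(ck2)
  L <- matrix(runif(32 * 32, -1, 1), 32)
  expect_identical(generatorForward(g1, L), generatorForward(g2, L))
  # variant 1 builds a CBAM-free generator
  expect_false(g1@config$cbam)
})
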