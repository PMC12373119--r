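# Channel splitting, Organalysis-style measurements and difference%.

test_that("channel splitting is lossless and carries the reporter roles", {
  img <- RgbImage(array(c(10, 255, 0), c(1, 1, 3)))
  ch <- splitChannels(img)
  expect_equal(ch$R[1, 1], 10)
  expect_equal(ch$G[1, 1], 255)
  expect_equal(ch$B[1, 1], 0)
  roles <- attr(ch, "roles")
  expect_equal(unname(roles["R"]), "mOrange-EC")
  expect_equal(unname(roles["G"]), "GFP-CM")
  # pure green pixel
  g <- splitChannels(RgbImage(array(c(0, 255, 0), c(1, 1, 3))))
  expect_equal(c(g$R, g$G, g$B), c(0, 255, 0))
  # recombination reproduces the input exactly
  set.seed(1)
  px <- array(sample(0:255, 48, TRUE), c(4, 4, 3))
  ch2 <- splitChannels(RgbImage(px))
  rec <- array(c(ch2$R, ch2$G, ch2$B), c(4, 4, 3))
  expect_equal(rec, px)
})

test_that("the toy 10x10 plane yields the hand-counted five measurements", {
  plane <- matrix(0, 10, 10)
  plane[1:5, 1:5] <- 200          # 25 pixels at 200
  m <- measureChannel(plane, threshold = 10)
  expect_equal(m@organoidArea, 25)
  expect_equal(m@pctCoverage, 25)
  expect_equal(m@totalIntensity, 5000)
  expect_equal(m@intensityByArea, 200)
  expect_equal(m@intensityByImageArea, 50)
})

test_that("empty masks give an explicit undefined ratio, never zero", {
  m <- measureChannel(matrix(0, 8, 8))
  expect_equal(m@organoidArea, 0)
  expect_equal(m@pctCoverage, 0)
  expect_true(is.na(m@intensityByArea))
  expect_equal(m@intensityByImageArea, 0)
})

test_that("a pixel exactly at the threshold is background (strict >)", {
  plane <- matrix(c(10, 11, 0, 0), 2, 2)
  m <- measureChannel(plane, threshold = 10)
  expect_equal(m@organoidArea, 1)
  expect_equal(m@totalIntensity, 11)
})

test_that("area and intensity are non-increasing in the threshold", {
  set.seed(7)
  plane <- matrix(sample(0:255, 400, TRUE), 20, 20)
  ts <- c(0, 10, 50, 128, 250)
  areas <- sapply(ts, function(t) measureChannel(plane, t)@organoidArea)
  totals <- sapply(ts, function(t) measureChannel(plane, t)@totalIntensity)
  expect_true(all(diff(areas) <= 0))
  expect_true(all(diff(totals) <= 0))
})

test_that("difference% identities, boundary classification and sentinels", {
  plane <- matrix(0, 10, 10); plane[1:5, 1:5] <- 200
  m <- measureChannel(plane)
  d0 <- differencePct(m, m)
  expect_true(all(d0$differencePct == 0))
  expect_true(all(d0$classification == "low"))
  # area 125 vs 100 -> 25%, on the boundary, classified low
  a <- matrix(0, 20, 20); a[seq_len(125)] <- 100
  b <- matrix(0, 20, 20); b[seq_len(100)] <- 100
  d <- differencePct(measureChannel(a), measureChannel(b))
  area <- d[d$metric == "organoidArea", ]
  expect_equal(area$differencePct, 25)
  expect_equal(area$classification, "low")
  # ground truth 0 -> undefined, never infinite
  dz <- differencePct(measureChannel(a), measureChannel(matrix(0, 20, 20)))
  expect_true(all(is.na(dz$differencePct)))
})

test_that("difference% is scale-consistent and area/coverage agree", {
  a <- matrix(0, 16, 16); a[1:40] <- 150
  b <- matrix(0, 16, 16); b[1:64] <- 90
  d1 <- differencePct(measureChannel(a), measureChannel(b))
  # doubling image scale of both measurement vectors leaves diff% unchanged
  big <- function(p) { q <- matrix(0, 16, 32); q[, 1:16] <- p; q[, 17:32] <- p; q }
  d2 <- differencePct(measureChannel(big(a)), measureChannel(big(b)))
  expect_equal(d1$differencePct[d1$metric == "organoidArea"],
               d2$differencePct[d2$metric == "organoidArea"])
  expect_equal(d1$differencePct[d1$metric == "organoidArea"],
               d1$differencePct[d1$metric == "pctCoverage"])
})

test_that("quantifyPair tabulates both reporter channels", {
  set.seed(9)
  gen <- RgbImage(array(sample(0:255, 32 * 32 * 3, TRUE), c(32, 32, 3)))
  q <- quantifyPair(gen, gen)
  expect_setequal(unique(q$channel), c("R", "G"))
  expect_true(all(q$differencePct == 0))
})
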