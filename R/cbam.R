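# Convolutional block attention: sequential channel attention
# (sigmoid(MLP(avgpool) + MLP(maxpool)), shared MLP with reduction ratio r)
# followed by spatial attention (sigmoid of a 7x7 convolution over the
# channel-wise [avg; max] stack), each applied by element-wise multiplication:
#   F' = Mc (x) F,   F'' = Ms (x) F'
# Geometry is always preserved: Mc is C x 1 x 1, Ms is 1 x H x W.

.cbamLayer <- function(channels, reduction = 16L, zero = FALSE, sd = 0.02) {
  if (reduction < 1 || channels %% reduction != 0)
    stop("CBAM reduction ratio ", reduction,
         " incompatible with ", channels, " channels")
  hidden <- max(1L, channels %/% reduction)
  l <- new.env(parent = emptyenv())
  l$type <- "cbam"
  l$c <- channels; l$hidden <- hidden
  l$w1 <- .newParam(.initW(hidden, channels, sd, zero))
  l$w2 <- .newParam(.initW(channels, hidden, sd, zero))
  l$conv <- .convLayer(2L, 1L, k = 7L, stride = 1L, pad = 3L, sd = sd, zero = zero)
  l
}

.cbamParams <- function(l) c(list(l$w1, l$w2), .layerParams(l$conv))

.cbamFwd <- function(l, x) {
  d <- dim(x)
  C <- d[1]; H <- d[2]; W <- d[3]; N <- d[4]
  hw <- H * W
  xr <- array(x, c(C, hw, N))
  pa <- matrix(0, C, N); pm <- matrix(0, C, N)
  amax <- matrix(0L, C, N)
  for (n in seq_len(N)) {
    m <- matrix(xr[, , n], C, hw)
    pa[, n] <- rowMeans(m)
    amax[, n] <- max.col(m, ties.method = "first")
    pm[, n] <- m[cbind(seq_len(C), amax[, n])]
  }
  haPre <- l$w1$p %*% pa; hmPre <- l$w1$p %*% pm
  ha <- pmax(haPre, 0); hm <- pmax(hmPre, 0)
  u <- l$w2$p %*% (ha + hm)
  s <- 1 / (1 + exp(-u))                       # Mc, one weight per channel
  f1 <- xr * aperm(array(s, c(C, N, hw)), c(1, 3, 2))
  avgc <- matrix(0, hw, N); maxc <- matrix(0, hw, N)
  cmax <- matrix(0L, hw, N)
  for (n in seq_len(N)) {
    m <- matrix(f1[, , n], C, hw)
    avgc[, n] <- colMeans(m)
    cmax[, n] <- max.col(t(m), ties.method = "first")
    maxc[, n] <- m[cbind(cmax[, n], seq_len(hw))]
  }
  stack <- array(0, c(2L, H, W, N))
  stack[1, , , ] <- array(avgc, c(H, W, N))
  stack[2, , , ] <- array(maxc, c(H, W, N))
  z <- .layerFwd(l$conv, stack)
  ms <- 1 / (1 + exp(-z))                      # Ms, 1 x H x W per sample
  msr <- array(ms, c(hw, N))
  f2 <- f1 * aperm(array(msr, c(hw, N, C)), c(3, 1, 2))
  l$x <- xr; l$pa <- pa; l$pm <- pm; l$amax <- amax
  l$haPre <- haPre; l$hmPre <- hmPre; l$ha <- ha; l$hm <- hm
  l$s <- s; l$f1 <- f1; l$cmax <- cmax; l$ms <- msr; l$shape <- d
  y <- array(f2, d)
  attr(y, "Mc") <- s
  attr(y, "Ms") <- array(ms, c(1L, H, W, N))
  y
}

.cbamBwd <- function(l, dy) {
  d <- l$shape
  C <- d[1]; H <- d[2]; W <- d[3]; N <- d[4]
  hw <- H * W
  dyr <- array(dy, c(C, hw, N))
  msb <- aperm(array(l$ms, c(hw, N, C)), c(3, 1, 2))
  df1 <- dyr * msb
  dms <- matrix(0, hw, N)
  for (n in seq_len(N))
    dms[, n] <- colSums(matrix(dyr[, , n] * l$f1[, , n], C, hw))
  dz <- dms * l$ms * (1 - l$ms)
  dstack <- .layerBwd(l$conv, array(dz, c(1L, H, W, N)))
  davg <- array(dstack[1, , , ], c(hw, N))
  dmax <- array(dstack[2, , , ], c(hw, N))
  df1 <- df1 + aperm(array(davg / C, c(hw, N, C)), c(3, 1, 2))
  for (n in seq_len(N)) {
    idx <- cbind(l$cmax[, n], seq_len(hw))
    m <- matrix(df1[, , n], C, hw)
    m[idx] <- m[idx] + dmax[, n]
    df1[, , n] <- m
  }
  # channel-attention path
  ds <- matrix(0, C, N)
  for (n in seq_len(N))
    ds[, n] <- rowSums(matrix(df1[, , n] * l$x[, , n], C, hw))
  dxr <- df1 * aperm(array(l$s, c(C, N, hw)), c(1, 3, 2))
  du <- ds * l$s * (1 - l$s)
  l$w2$g <- l$w2$g + du %*% t(l$ha + l$hm)
  dh <- t(l$w2$p) %*% du
  dhaPre <- dh * (l$haPre > 0)
  dhmPre <- dh * (l$hmPre > 0)
  l$w1$g <- l$w1$g + dhaPre %*% t(l$pa) + dhmPre %*% t(l$pm)
  dpa <- t(l$w1$p) %*% dhaPre
  dpm <- t(l$w1$p) %*% dhmPre
  dxr <- dxr + aperm(array(dpa / hw, c(C, N, hw)), c(1, 3, 2))
  for (n in seq_len(N)) {
    idx <- cbind(seq_len(C), l$amax[, n])
    m <- matrix(dxr[, , n], C, hw)
    m[idx] <- m[idx] + dpm[, n]
    dxr[, , n] <- m
  }
  array(dxr, d)
}

#' Create a CBAM attention block
#'
#' @param channels number of feature-map channels C.
#' @param reduction channel-attention reduction ratio r (hidden width C/r);
#'   must divide `channels`.
#' @param init `"random"` (default, N(0, 0.02) weights) or `"zero"` (all
#'   parameters zero, so both attention gates output exactly 0.5 everywhere).
#' @return An opaque CBAM block usable with [cbamRefine()].
#' @export
cbamLayer <- function(channels, reduction = 16L, init = c("random", "zero")) {
  init <- match.arg(init)
  .cbamLayer(as.integer(channels), as.integer(reduction), zero = init == "zero")
}

#' Refine a feature map with channel and spatial attention
#'
#' Applies the two-stage attention F' = Mc (x) F, F'' = Ms (x) F' where Mc
#' (C x 1 x 1) rescales channels and Ms (1 x H x W) rescales spatial
#' locations, both bounded in (0, 1) by the sigmoid.  The output has exactly
#' the shape of the input.
#'
#' @param feature numeric array, either (C, H, W) for a single feature map or
#'   (C, H, W, N) for a batch.
#' @param block a block from [cbamLayer()].
#' @return list with `refined` (same shape as `feature`), `Mc` (C x 1 x 1
#'   array, per batch sample) and `Ms` (1 x H x W array, per batch sample).
#' @export
cbamRefine <- function(feature, block) {
  d <- dim(feature)
  single <- length(d) == 3L
  if (single) dim(feature) <- c(d, 1L)
  if (dim(feature)[1] != block$c)
    stop("feature map has ", dim(feature)[1], " channels, block expects ", block$c)
  if (any(!is.finite(feature))) stop("feature map must be finite")
  y <- .cbamFwd(block, feature)
  mc <- attr(y, "Mc"); ms <- attr(y, "Ms")
  attributes(y)[c("Mc", "Ms")] <- NULL
  if (single) {
    dim(y) <- d
    mc <- array(mc[, 1], c(block$c, 1L, 1L))
    ms <- array(ms[, , , 1], c(1L, d[2], d[3]))
  } else {
    mc <- array(mc, c(block$c, 1L, 1L, dim(feature)[4]))
  }
  list(refined = y, Mc = mc, Ms = ms)
}
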