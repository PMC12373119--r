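# U-Net generator (Lightness-conditioned, a*/b* output) and the patch
# discriminator.  Both are built from the layer primitives in nn.R; forward
# passes cache what the hand-written backward passes need.

.isPow2 <- function(n) n >= 1 && bitwAnd(n, n - 1L) == 0L

# largest divisor of C not exceeding r: keeps the channel-attention MLP
# well-formed when blocks are narrower than the nominal reduction ratio
.fitReduction <- function(C, r) {
  r <- min(r, C)
  while (C %% r != 0) r <- r - 1L
  as.integer(r)
}

#' Build a U-Net generator
#'
#' Encoder: stride-2 4x4 convolutions with LeakyReLU(0.2), channel widths
#' base * min(2^(i-1), 8); decoder: mirrored stride-2 transposed convolutions
#' with ReLU and skip concatenation; tanh squashes the 2-channel a*/b* output
#' into [-1, 1].  Instance normalization is applied except on the first
#' encoder layer and on maps whose spatial extent has collapsed to 1 x 1.
#' With `cbam = TRUE` every skip connection and the bottleneck are refined by
#' a CBAM block before re-entering the decoder.
#'
#' @param size input image side in pixels; must be a power of two >= 4.
#' @param base channels of the first encoder layer (64 matches the reference
#'   backbone at 256 x 256; smaller values suit desk-scale synthetic images).
#' @param depth number of downsampling steps; default log2(size) (1 x 1
#'   bottleneck), automatically reduced for small images.
#' @param cbam logical, attach CBAM blocks to skips and bottleneck.
#' @param cbamReduction nominal channel-attention reduction ratio.
#' @param seed integer seed for weight initialization (N(0, 0.02)).
#' @return A [GeneratorNet-class].
#' @export
buildGenerator <- function(size, base = 64L, depth = NULL, cbam = TRUE,
                           cbamReduction = 16L, seed = 1L) {
  size <- as.integer(size)
  if (!.isPow2(size) || size < 4L)
    stop("generator input size must be a power of two >= 4, got ", size)
  maxDepth <- as.integer(log2(size))
  depth <- as.integer(depth %||% maxDepth)
  if (depth < 2L || depth > maxDepth)
    stop("depth must lie in [2, log2(size)]")
  encC <- as.integer(base * pmin(2^(seq_len(depth) - 1L), 8L))
  .withSeed(seed, {
    enc <- vector("list", depth); encNorm <- vector("list", depth)
    encAct <- vector("list", depth)
    for (i in seq_len(depth)) {
      cin <- if (i == 1L) 1L else encC[i - 1L]
      enc[[i]] <- .convLayer(cin, encC[i])
      sp <- size / 2^i
      if (i > 1L && sp > 1) encNorm[[i]] <- .inormLayer(encC[i])
      encAct[[i]] <- .actLayer("lrelu")
    }
    dec <- vector("list", depth); decNorm <- vector("list", depth)
    decAct <- vector("list", depth)
    for (i in seq(depth, 1L)) {
      cin <- if (i == depth) encC[depth] else 2L * encC[i]
      cout <- if (i > 1L) encC[i - 1L] else 2L
      dec[[i]] <- .convtLayer(cin, cout)
      if (i > 1L) {
        decNorm[[i]] <- .inormLayer(cout)
        decAct[[i]] <- .actLayer("relu")
      }
    }
    outAct <- .actLayer("tanh")
    cb <- NULL
    if (cbam)
      cb <- lapply(encC, function(C)
        .cbamLayer(C, .fitReduction(C, as.integer(cbamReduction))))
    new("GeneratorNet",
        config = list(size = size, base = as.integer(base), depth = depth,
                      cbam = cbam, cbamReduction = as.integer(cbamReduction),
                      encC = encC, seed = as.integer(seed)),
        layers = list(enc = enc, encNorm = encNorm, encAct = encAct,
                      dec = dec, decNorm = decNorm, decAct = decAct,
                      outAct = outAct, cb = cb))
  })
}

.genForward <- function(net, x) {
  L <- net@layers
  depth <- net@config$depth
  e <- vector("list", depth)
  u <- x
  for (i in seq_len(depth)) {
    u <- .layerFwd(L$enc[[i]], u)
    if (!is.null(L$encNorm[[i]])) u <- .layerFwd(L$encNorm[[i]], u)
    u <- .layerFwd(L$encAct[[i]], u)
    e[[i]] <- u
  }
  skips <- e
  if (!is.null(L$cb))
    for (i in seq_len(depth)) {
      s <- .layerFwd(L$cb[[i]], e[[i]])
      attributes(s)[c("Mc", "Ms")] <- NULL
      skips[[i]] <- s
    }
  u <- skips[[depth]]
  for (i in seq(depth, 1L)) {
    u <- .layerFwd(L$dec[[i]], u)
    if (i > 1L) {
      u <- .layerFwd(L$decNorm[[i]], u)
      u <- .layerFwd(L$decAct[[i]], u)
      sk <- skips[[i - 1L]]
      cu <- dim(u)[1]; cs <- dim(sk)[1]
      v <- array(0, c(cu + cs, dim(u)[2], dim(u)[3], dim(u)[4]))
      v[seq_len(cu), , , ] <- u
      v[cu + seq_len(cs), , , ] <- sk
      u <- v
    } else {
      u <- .layerFwd(L$outAct, u)
    }
  }
  u
}

.genBackward <- function(net, dy) {
  L <- net@layers
  depth <- net@config$depth
  encC <- net@config$encC
  dskips <- vector("list", depth)
  # decoder, reversed
  g <- .layerBwd(L$outAct, dy)
  g <- .layerBwd(L$dec[[1L]], g)
  for (i in seq(1L, depth)) {
    if (i > 1L) {
      g <- .layerBwd(L$decAct[[i]], g)
      g <- .layerBwd(L$decNorm[[i]], g)
      g <- .layerBwd(L$dec[[i]], g)
    }
    if (i < depth) {
      cu <- encC[i]
      dw <- g[seq_len(cu), , , , drop = FALSE]
      dskips[[i]] <- g[cu + seq_len(cu), , , , drop = FALSE]
      g <- dw
    } else {
      dskips[[depth]] <- g
    }
  }
  dE <- dskips
  if (!is.null(L$cb))
    for (i in seq_len(depth)) dE[[i]] <- .layerBwd(L$cb[[i]], dskips[[i]])
  g <- NULL
  for (i in seq(depth, 1L)) {
    gi <- if (is.null(g)) dE[[i]] else dE[[i]] + g
    gi <- .layerBwd(L$encAct[[i]], gi)
    if (!is.null(L$encNorm[[i]])) gi <- .layerBwd(L$encNorm[[i]], gi)
    g <- .layerBwd(L$enc[[i]], gi)
  }
  g
}

#' Run the generator on a normalized Lightness plane
#'
#' @param net a [GeneratorNet-class].
#' @param L normalized Lightness input in [-1, 1]: an H x W matrix, or a
#'   (1, H, W, N) array for a batch.
#' @return For matrix input a (2, H, W) array (a* then b* plane, values in
#'   (-1, 1)); for batch input a (2, H, W, N) array.  Deterministic given the
#'   network parameters.
#' @export
generatorForward <- function(net, L) {
  single <- is.matrix(L)
  x <- if (single) array(L, c(1L, nrow(L), ncol(L), 1L)) else .asTensor(L)
  d <- dim(x)
  if (d[2] != d[3] || !.isPow2(d[2]))
    stop("generator input must be square with power-of-two side, got ",
         d[2], " x ", d[3])
  if (d[2] != net@config$size)
    stop("network was built for ", net@config$size, " px inputs, got ", d[2])
  if (max(abs(x)) > 1 + 1e-9)
    stop("Lightness input must be normalized to [-1, 1]")
  y <- .genForward(net, x)
  if (single) array(y, dim(y)[1:3]) else y
}

#' Build a patch discriminator
#'
#' Five 4x4 convolutions (strides 2,2,2,1,1; widths base * 1,2,4,8 then 1)
#' with LeakyReLU(0.2) and instance normalization; every output unit scores
#' a local 70 x 70-pixel receptive field, giving a 30 x 30 patch-score map on
#' 256 x 256 input.
#'
#' @param inChannels input channels: 3 when conditioning on L stacked with
#'   a*b* (default pipeline), 2 for the ab-only variant.
#' @param base width of the first layer.
#' @param seed integer seed for weight initialization.
#' @return A [DiscriminatorNet-class].
#' @export
buildDiscriminator <- function(inChannels = 3L, base = 64L, seed = 1L) {
  strides <- c(2L, 2L, 2L, 1L, 1L)
  widths <- c(base, 2L * base, 4L * base, 8L * base, 1L)
  .withSeed(seed, {
    layers <- list()
    cin <- as.integer(inChannels)
    for (j in seq_along(strides)) {
      layers[[length(layers) + 1L]] <-
        .convLayer(cin, widths[j], k = 4L, stride = strides[j], pad = 1L)
      if (j < length(strides)) {
        if (j > 1L)
          layers[[length(layers) + 1L]] <- .inormLayer(widths[j])
        layers[[length(layers) + 1L]] <- .actLayer("lrelu")
      }
      cin <- widths[j]
    }
    new("DiscriminatorNet",
        config = list(inChannels = as.integer(inChannels),
                      base = as.integer(base), seed = as.integer(seed)),
        layers = layers)
  })
}

.discForwardLogits <- function(net, x) {
  u <- x
  for (l in net@layers) u <- .layerFwd(l, u)
  u
}

.discBackward <- function(net, dy) {
  g <- dy
  for (l in rev(net@layers)) g <- .layerBwd(l, g)
  g
}

# stack condition (may be NULL in ab-only mode) with the chromatic planes
.discInput <- function(condition, ab) {
  if (is.null(condition)) return(ab)
  d <- dim(ab)
  if (is.matrix(condition)) {
    if (!identical(dim(condition), d[2:3]))
      stop("condition and ab planes are spatially misaligned")
    condition <- array(condition, c(1L, d[2], d[3], d[4]))
  }
  if (!all(dim(condition)[2:3] == d[2:3]))
    stop("condition and ab planes are spatially misaligned")
  v <- array(0, c(1L + d[1], d[2], d[3], d[4]))
  v[1L, , , ] <- condition
  v[1L + seq_len(d[1]), , , ] <- ab
  v
}

#' Score an image with the patch discriminator
#'
#' @param net a [DiscriminatorNet-class].
#' @param condition normalized Lightness plane (H x W matrix or
#'   (1, H, W, N) array), or `NULL` for the ab-only variant.
#' @param ab chromatic planes, (2, H, W) or (2, H, W, N).
#' @return list with `patchScores` (the sigmoid patch-probability map,
#'   Ho x Wo matrix for single input) and `meanScore`, the arithmetic mean of
#'   the patch scores — the image-level "global classification score".
#' @export
discriminatorForward <- function(net, condition, ab) {
  single <- length(dim(ab)) == 3L
  if (single) {
    dim(ab) <- c(dim(ab), 1L)
    if (!is.null(condition) && !is.matrix(condition))
      stop("for single images pass the condition as an H x W matrix")
  }
  x <- .discInput(condition, ab)
  if (dim(x)[1] != net@config$inChannels)
    stop("discriminator expects ", net@config$inChannels, " input channels, got ",
         dim(x)[1])
  z <- .discForwardLogits(net, x)
  s <- 1 / (1 + exp(-z))
  if (single) {
    m <- matrix(s[1L, , , 1L], dim(s)[2], dim(s)[3])
    list(patchScores = m, meanScore = mean(m))
  } else {
    list(patchScores = s,
         meanScore = apply(s, 4, mean))
  }
}

.netParamCells <- function(net) {
  cells <- list()
  walk <- function(x) {
    if (is.environment(x)) cells[length(cells) + seq_along(.layerParams(x))] <<- .layerParams(x)
    else if (is.list(x)) for (el in x) if (!is.null(el)) walk(el)
  }
  walk(net@layers)
  cells
}

#' Total number of trainable parameters of a network
#' @param net a [GeneratorNet-class] or [DiscriminatorNet-class].
#' @return integer count.
#' @export
countParams <- function(net) {
  sum(vapply(.netParamCells(net), function(p) length(p$p), numeric(1)))
}

# plain-array snapshot of all parameters (for checkpoints)
.netSnapshot <- function(net) lapply(.netParamCells(net), function(p) p$p)

.netRestore <- function(net, snapshot) {
  cells <- .netParamCells(net)
  stopifnot(length(cells) == length(snapshot))
  for (i in seq_along(cells)) {
    stopifnot(length(cells[[i]]$p) == length(snapshot[[i]]))
    cells[[i]]$p <- snapshot[[i]]
    cells[[i]]$m <- cells[[i]]$m * 0
    cells[[i]]$v <- cells[[i]]$v * 0
  }
  invisible(net)
}
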