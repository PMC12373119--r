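# Minimal reference-semantics layer framework.  Tensors are numeric arrays
# with dim = c(C, H, W, N); every layer is an environment holding parameter
# cells, Adam state and the forward cache needed by its backward pass.
# The convolution kernels live in src/convops.cpp.

.newParam <- function(value) {
  e <- new.env(parent = emptyenv())
  e$p <- value
  e$g <- value * 0
  e$m <- e$g
  e$v <- e$g
  e
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.asTensor <- function(x) {
  if (length(dim(x)) == 4L) return(x)
  stop("expected a (C,H,W,N) tensor")
}

.initW <- function(nr, nc, sd, zero = FALSE) {
  if (zero) matrix(0, nr, nc) else matrix(stats::rnorm(nr * nc, 0, sd), nr, nc)
}

# --- layer constructors ------------------------------------------------------

.convLayer <- function(cin, cout, k = 4L, stride = 2L, pad = 1L,
                       sd = 0.02, zero = FALSE) {
  l <- new.env(parent = emptyenv())
  l$type <- "conv"
  l$k <- as.integer(k); l$stride <- as.integer(stride); l$pad <- as.integer(pad)
  l$cin <- cin; l$cout <- cout
  l$w <- .newParam(.initW(cout, cin * k * k, sd, zero))
  l$b <- .newParam(numeric(cout))
  l
}

.convtLayer <- function(cin, cout, k = 4L, stride = 2L, pad = 1L,
                        sd = 0.02, zero = FALSE) {
  l <- new.env(parent = emptyenv())
  l$type <- "convt"
  l$k <- as.integer(k); l$stride <- as.integer(stride); l$pad <- as.integer(pad)
  l$cin <- cin; l$cout <- cout
  l$w <- .newParam(.initW(cin, cout * k * k, sd, zero))
  l$b <- .newParam(numeric(cout))
  l
}

# instance normalization: per sample and channel over the spatial plane
.inormLayer <- function(c, eps = 1e-5) {
  l <- new.env(parent = emptyenv())
  l$type <- "inorm"
  l$c <- c; l$eps <- eps
  l$gamma <- .newParam(rep(1, c))
  l$beta <- .newParam(numeric(c))
  l
}

.actLayer <- function(kind, alpha = 0.2) {
  l <- new.env(parent = emptyenv())
  l$type <- kind           # "lrelu", "relu", "tanh", "sigmoid"
  l$alpha <- alpha
  l
}

.layerParams <- function(l) {
  switch(l$type,
         conv = , convt = list(l$w, l$b),
         inorm = list(l$gamma, l$beta),
         cbam = .cbamParams(l),
         list())
}

# --- forward / backward ------------------------------------------------------

.layerFwd <- function(l, x) {
  switch(l$type,
    conv = {
      l$x <- x
      cpp_conv_fwd(x, l$w$p, l$b$p, l$k, l$stride, l$pad)
    },
    convt = {
      l$x <- x
      d <- dim(x)
      hout <- l$stride * (d[2] - 1L) + l$k - 2L * l$pad
      wout <- l$stride * (d[3] - 1L) + l$k - 2L * l$pad
      cpp_convt_fwd(x, l$w$p, l$b$p, l$k, l$stride, l$pad, hout, wout)
    },
    inorm = {
      d <- dim(x)
      C <- d[1]; hw <- d[2] * d[3]; N <- d[4]
      xr <- array(x, c(C, hw, N))
      mu <- vapply(seq_len(N), function(n) rowMeans(xr[, , n, drop = FALSE]),
                   numeric(C))
      mu <- matrix(mu, C, N)
      # broadcast (C,N) statistics over the spatial axis
      ctr <- xr - aperm(array(mu, c(C, N, hw)), c(1, 3, 2))
      v <- vapply(seq_len(N), function(n) rowMeans(ctr[, , n, drop = FALSE]^2),
                  numeric(C))
      v <- matrix(v, C, N)
      isd <- 1 / sqrt(v + l$eps)
      xhat <- ctr * aperm(array(isd, c(C, N, hw)), c(1, 3, 2))
      l$xhat <- xhat; l$isd <- isd; l$shape <- d
      y <- xhat * l$gamma$p + l$beta$p   # gamma/beta length C recycle over C-fastest axis
      array(y, d)
    },
    lrelu = { l$x <- x; ifelse(x > 0, x, l$alpha * x) },
    relu = { l$x <- x; pmax(x, 0) },
    tanh = { l$y <- tanh(x); l$y },
    sigmoid = { l$y <- 1 / (1 + exp(-x)); l$y },
    cbam = .cbamFwd(l, x),
    stop("unknown layer type ", l$type))
}

.layerBwd <- function(l, dy) {
  switch(l$type,
    conv = {
      r <- cpp_conv_bwd(l$x, l$w$p, dy, l$k, l$stride, l$pad)
      l$w$g <- l$w$g + r$dw
      l$b$g <- l$b$g + r$db
      r$dx
    },
    convt = {
      r <- cpp_convt_bwd(l$x, l$w$p, dy, l$k, l$stride, l$pad)
      l$w$g <- l$w$g + r$dw
      l$b$g <- l$b$g + r$db
      r$dx
    },
    inorm = {
      d <- l$shape
      C <- d[1]; hw <- d[2] * d[3]; N <- d[4]
      dyr <- array(dy, c(C, hw, N))
      xhat <- l$xhat
      dgamma <- numeric(C); dbeta <- numeric(C)
      dx <- array(0, c(C, hw, N))
      for (n in seq_len(N)) {
        dyn <- matrix(dyr[, , n], C, hw)
        xh <- matrix(xhat[, , n], C, hw)
        dgamma <- dgamma + rowSums(dyn * xh)
        dbeta <- dbeta + rowSums(dyn)
        dxh <- dyn * l$gamma$p
        mdy <- rowMeans(dxh)
        mdyx <- rowMeans(dxh * xh)
        dx[, , n] <- (dxh - mdy - xh * mdyx) * l$isd[, n]
      }
      l$gamma$g <- l$gamma$g + dgamma
      l$beta$g <- l$beta$g + dbeta
      array(dx, d)
    },
    lrelu = dy * ifelse(l$x > 0, 1, l$alpha),
    relu = dy * (l$x > 0),
    tanh = dy * (1 - l$y^2),
    sigmoid = dy * l$y * (1 - l$y),
    cbam = .cbamBwd(l, dy),
    stop("unknown layer type ", l$type))
}

# --- optimizer ---------------------------------------------------------------

.zeroGrads <- function(cells) {
  for (p in cells) p$g <- p$g * 0
  invisible(NULL)
}

.adamStep <- function(cells, lr, beta1, beta2, eps, t) {
  b1t <- 1 - beta1^t
  b2t <- 1 - beta2^t
  for (p in cells) {
    p$m <- beta1 * p$m + (1 - beta1) * p$g
    p$v <- beta2 * p$v + (1 - beta2) * p$g^2
    p$p <- p$p - lr * (p$m / b1t) / (sqrt(p$v / b2t) + eps)
  }
  invisible(NULL)
}

# run an expression under a fixed seed, restoring the caller's RNG state
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  force(expr)
}
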