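## Minimal CPU neural-network core for the DCGAN.
##
## Design notes:
##  - Dense tensors are D x N matrices (features in rows, batch in
##    columns) so per-unit vectors broadcast down columns for free.
##  - Convolutional tensors are H x W x C x N arrays.
##  - conv / transposed conv use precomputed-index im2col / col2im so the
##    inner loops are single indexed gathers/scatters plus one BLAS
##    matrix multiplication over the whole batch.  A transposed
##    convolution is implemented exactly as the adjoint of the
##    corresponding stride-2 convolution.
##  - "Same" padding for kernel 5 / stride 2 needs an asymmetric total
##    pad of 3 (1 before, 2 after) in each spatial dimension.
##  - Layers are plain tagged lists (serializable, hashable); networks are
##    lists of layers plus an Adam step counter.  Backward accumulates
##    gradients so a discriminator update can sum real-batch and
##    fake-batch passes.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1   # running <- (1 - m) * running + m * batch
ADAM_EPS <- 1e-8
INIT_SD <- 0.02      # N(0, 0.02) weight init, standard DCGAN choice

## ---- convolution geometry ----

## Spatial gather indices for a k x k, stride-s "same" convolution.
## p runs column-major over the output grid (output row fastest); offset
## o runs with the kernel-row offset fastest.
convGeom <- function(inH, inW, k = 5L, s = 2L) {
  outH <- as.integer(ceiling(inH / s))
  outW <- as.integer(ceiling(inW / s))
  padH <- max((outH - 1L) * s + k - inH, 0L)
  padW <- max((outW - 1L) * s + k - inW, 0L)
  padT <- padH %/% 2L
  padL <- padW %/% 2L
  Hp <- inH + padH
  Wp <- inW + padW
  P <- outH * outW
  oi <- rep(0:(outH - 1L), times = outW)
  oj <- rep(0:(outW - 1L), each = outH)
  idx <- matrix(0L, P, k * k)
  o <- 0L
  for (dj in 0:(k - 1L)) for (di in 0:(k - 1L)) {
    o <- o + 1L
    idx[, o] <- (oj * s + dj) * Hp + (oi * s + di) + 1L
  }
  ii <- rep(0:(inH - 1L), times = inW)
  jj <- rep(0:(inW - 1L), each = inH)
  inner <- (jj + padL) * Hp + (ii + padT) + 1L
  list(inH = inH, inW = inW, outH = outH, outW = outW, k = k, s = s,
       Hp = Hp, Wp = Wp, P = P, idx = idx, inner = inner)
}

## Batch gather/scatter plan for a given channel count and batch size.
convPlan <- function(geom, inC, N) {
  S <- geom$Hp * geom$Wp
  kk <- geom$k^2
  P <- geom$P
  ## idxFull: P x (kk*inC), column block o holds channels 1..inC
  idxFull <- matrix(0L, P, kk * inC)
  for (o in seq_len(kk)) {
    cols <- ((o - 1L) * inC + 1L):(o * inC)
    idxFull[, cols] <- geom$idx[, o] +
      matrix((0:(inC - 1L)) * S, P, inC, byrow = TRUE)
  }
  idxBig <- idxFull[rep(seq_len(P), times = N), , drop = FALSE] +
    rep((0:(N - 1L)) * (S * inC), each = P)
  innerFull <- rep(geom$inner, times = inC) +
    rep((0:(inC - 1L)) * S, each = geom$inH * geom$inW)
  innerBig <- rep(innerFull, times = N) +
    rep((0:(N - 1L)) * (S * inC), each = length(innerFull))
  list(S = S, kk = kk, P = P, inC = inC, N = N,
       idxBig = idxBig, innerBig = innerBig)
}

getPlan <- function(layer, N) {
  key <- as.character(N)
  if (is.null(layer$plans[[key]]))
    layer$plans[[key]] <- convPlan(layer$geom, layer$inC, N)
  layer
}

## gather the padded batch into the (N*P) x (kk*inC) column matrix
im2colBatch <- function(x, plan) {
  xp <- numeric(plan$S * plan$inC * plan$N)
  xp[plan$innerBig] <- x
  col <- xp[plan$idxBig]
  dim(col) <- c(plan$N * plan$P, plan$kk * plan$inC)
  col
}

## scatter-add the column matrix back onto the (unpadded) input grid;
## duplicates (overlapping kernel footprints) accumulate in C.
col2imBatch <- function(colB, plan, dims) {
  xp <- numeric(plan$S * plan$inC * plan$N)
  .scatterAdd(xp, plan$idxBig, colB)
  array(xp[plan$innerBig], dims)
}

## (P, N, C)-ordered matrix <-> (H, W, C, N) array
gridToRows <- function(x, P, C, N) {
  m <- aperm(array(x, c(P, C, N)), c(1L, 3L, 2L))
  dim(m) <- c(P * N, C)
  m
}
rowsToGrid <- function(m, H, W, C, N) {
  a <- aperm(array(m, c(H * W, N, C)), c(1L, 3L, 2L))
  dim(a) <- c(H, W, C, N)
  a
}

## ---- layer constructors ----

newDense <- function(inDim, outDim) {
  list(kind = "dense",
       W = matrix(stats::rnorm(inDim * outDim, 0, INIT_SD), inDim, outDim),
       b = numeric(outDim),
       params = c("W", "b"))
}

newBnDense <- function(dim) {
  list(kind = "bnDense", gamma = rep(1, dim), beta = numeric(dim),
       runMean = numeric(dim), runVar = rep(1, dim),
       params = c("gamma", "beta"))
}

newBnConv <- function(channels) {
  list(kind = "bnConv", gamma = rep(1, channels), beta = numeric(channels),
       runMean = numeric(channels), runVar = rep(1, channels),
       params = c("gamma", "beta"))
}

newConv <- function(inH, inW, inC, outC, k = 5L, s = 2L) {
  list(kind = "conv", geom = convGeom(inH, inW, k, s), inC = inC,
       outC = outC, plans = list(),
       W = matrix(stats::rnorm(k * k * inC * outC, 0, INIT_SD),
                  k * k * inC, outC),
       b = numeric(outC),
       params = c("W", "b"))
}

## transposed conv: coarse (cH x cW x coarseC) -> fine (2cH x 2cW x fineC);
## geometry/weights are those of the adjoint fine -> coarse convolution.
newTconv <- function(cH, cW, coarseC, fineC, k = 5L, s = 2L) {
  list(kind = "tconv", geom = convGeom(cH * s, cW * s, k, s), inC = fineC,
       coarseC = coarseC, fineC = fineC, plans = list(),
       W = matrix(stats::rnorm(k * k * fineC * coarseC, 0, INIT_SD),
                  k * k * fineC, coarseC),
       b = numeric(fineC),
       params = c("W", "b"))
}

newAct <- function(kind) list(kind = kind, params = character(0))

newReshape <- function(H, W, C)
  list(kind = "reshape", dims = c(H, W, C), params = character(0))

newFlatten <- function() list(kind = "flatten", params = character(0))

## ---- per-channel helpers for conv batch norm ----

chSums <- function(a, HW, C, N) {
  rowSums(matrix(colSums(matrix(a, HW, C * N)), C, N))
}
chExpand <- function(v, HW) rep(v, each = HW)  # recycles over batch dim

## ---- forward ----

layerForward <- function(l, x, train) {
  switch(l$kind,
    dense = {
      l$x <- x
      out <- crossprod(l$W, x) + l$b
      list(layer = l, out = out)
    },
    bnDense = {
      if (train) {
        mu <- rowMeans(x)
        xc <- x - mu
        v <- rowMeans(xc * xc)
        l$runMean <- (1 - BN_MOMENTUM) * l$runMean + BN_MOMENTUM * mu
        l$runVar <- (1 - BN_MOMENTUM) * l$runVar + BN_MOMENTUM * v
      } else {
        mu <- l$runMean
        xc <- x - mu
        v <- l$runVar
      }
      invstd <- 1 / sqrt(v + BN_EPS)
      xhat <- xc * invstd
      if (train) { l$xhat <- xhat; l$invstd <- invstd }
      list(layer = l, out = xhat * l$gamma + l$beta)
    },
    bnConv = {
      d <- dim(x)
      HW <- d[1] * d[2]; C <- d[3]; N <- d[4]; M <- HW * N
      if (train) {
        mu <- chSums(x, HW, C, N) / M
        xc <- x - chExpand(mu, HW)
        v <- chSums(xc * xc, HW, C, N) / M
        l$runMean <- (1 - BN_MOMENTUM) * l$runMean + BN_MOMENTUM * mu
        l$runVar <- (1 - BN_MOMENTUM) * l$runVar + BN_MOMENTUM * v
      } else {
        mu <- l$runMean
        xc <- x - chExpand(mu, HW)
        v <- l$runVar
      }
      invstd <- 1 / sqrt(v + BN_EPS)
      xhat <- xc * chExpand(invstd, HW)
      if (train) { l$xhat <- xhat; l$invstd <- invstd; l$M <- M }
      list(layer = l, out = xhat * chExpand(l$gamma, HW) +
             chExpand(l$beta, HW))
    },
    tanh = {
      out <- tanh(x)
      l$y <- out
      list(layer = l, out = out)
    },
    sigmoid = {
      out <- 1 / (1 + exp(-x))
      l$y <- out
      list(layer = l, out = out)
    },
    lrelu = {
      l$mask <- x > 0
      list(layer = l, out = ifelse(l$mask, x, 0.2 * x))
    },
    reshape = {
      list(layer = l, out = array(x, c(l$dims, ncol(x))))
    },
    flatten = {
      d <- dim(x)
      l$dims <- d[1:3]
      list(layer = l, out = matrix(x, prod(d[1:3]), d[4]))
    },
    conv = {
      d <- dim(x)
      N <- d[4]
      l <- getPlan(l, N)
      plan <- l$plans[[as.character(N)]]
      colB <- im2colBatch(x, plan)
      yB <- colB %*% l$W + rep(l$b, each = plan$N * plan$P)
      l$colB <- colB
      g <- l$geom
      list(layer = l, out = rowsToGrid(yB, g$outH, g$outW, l$outC, N))
    },
    tconv = {
      d <- dim(x)
      N <- d[4]
      l <- getPlan(l, N)
      plan <- l$plans[[as.character(N)]]
      g <- l$geom
      Pc <- d[1] * d[2]
      xB <- gridToRows(x, Pc, l$coarseC, N)
      colB <- tcrossprod(xB, l$W)           # (N*Pc) x (kk*fineC)
      y <- col2imBatch(colB, plan, c(g$inH, g$inW, l$fineC, N))
      y <- y + chExpand(l$b, g$inH * g$inW)
      l$xB <- xB
      list(layer = l, out = y)
    },
    stop("unknown layer kind: ", l$kind))
}

## ---- backward (gradients accumulate into g<param> slots) ----

accGrad <- function(l, name, g) {
  slot <- paste0("g", name)
  if (is.null(l[[slot]])) l[[slot]] <- g else l[[slot]] <- l[[slot]] + g
  l
}

layerBackward <- function(l, dout) {
  switch(l$kind,
    dense = {
      l <- accGrad(l, "W", tcrossprod(l$x, dout))
      l <- accGrad(l, "b", rowSums(dout))
      list(layer = l, dx = l$W %*% dout)
    },
    bnDense = {
      N <- ncol(dout)
      dxhat <- dout * l$gamma
      t1 <- rowSums(dxhat)
      t2 <- rowSums(dxhat * l$xhat)
      dx <- l$invstd * (dxhat - t1 / N - l$xhat * (t2 / N))
      l <- accGrad(l, "gamma", rowSums(dout * l$xhat))
      l <- accGrad(l, "beta", rowSums(dout))
      list(layer = l, dx = dx)
    },
    bnConv = {
      d <- dim(dout)
      HW <- d[1] * d[2]; C <- d[3]; N <- d[4]; M <- l$M
      dxhat <- dout * chExpand(l$gamma, HW)
      t1 <- chSums(dxhat, HW, C, N)
      t2 <- chSums(dxhat * l$xhat, HW, C, N)
      dx <- chExpand(l$invstd, HW) *
        (dxhat - chExpand(t1 / M, HW) - l$xhat * chExpand(t2 / M, HW))
      l <- accGrad(l, "gamma", chSums(dout * l$xhat, HW, C, N))
      l <- accGrad(l, "beta", chSums(dout, HW, C, N))
      list(layer = l, dx = dx)
    },
    tanh = list(layer = l, dx = dout * (1 - l$y^2)),
    sigmoid = list(layer = l, dx = dout * l$y * (1 - l$y)),
    lrelu = list(layer = l, dx = dout * ifelse(l$mask, 1, 0.2)),
    reshape = list(layer = l,
                   dx = matrix(dout, prod(l$dims), dim(dout)[4])),
    flatten = list(layer = l, dx = array(dout, c(l$dims, ncol(dout)))),
    conv = {
      d <- dim(dout)
      N <- d[4]
      plan <- l$plans[[as.character(N)]]
      g <- l$geom
      dyB <- gridToRows(dout, g$P, l$outC, N)
      l <- accGrad(l, "W", crossprod(l$colB, dyB))
      l <- accGrad(l, "b", colSums(dyB))
      dcolB <- tcrossprod(dyB, l$W)
      dx <- col2imBatch(dcolB, plan, c(g$inH, g$inW, l$inC, N))
      list(layer = l, dx = dx)
    },
    tconv = {
      d <- dim(dout)
      N <- d[4]
      plan <- l$plans[[as.character(N)]]
      g <- l$geom
      HWf <- g$inH * g$inW
      dyp <- numeric(plan$S * plan$inC * plan$N)
      dyp[plan$innerBig] <- dout
      colDy <- matrix(dyp[plan$idxBig], N * g$P, plan$kk * plan$inC)
      dxB <- colDy %*% l$W                  # (N*Pc) x coarseC
      l <- accGrad(l, "W", crossprod(colDy, l$xB))
      l <- accGrad(l, "b", chSums(dout, HWf, l$fineC, N))
      dx <- rowsToGrid(dxB, g$outH, g$outW, l$coarseC, N)
      list(layer = l, dx = dx)
    },
    stop("unknown layer kind: ", l$kind))
}

## ---- network plumbing ----

newNet <- function(layers) list(layers = layers, t = 0L)

#' Run a layer stack forward
#'
#' Low-level forward pass through a generator or discriminator parameter
#' stack as returned by [buildGenerator()] / [buildDiscriminator()].
#'
#' @param net a network (list of layers plus Adam step counter).
#' @param x input tensor: latent matrix `zDim x n` for the generator, or
#'   image array `64 x 64 x 3 x n` for the discriminator.
#' @param train logical; `TRUE` uses batch statistics in the batch-norm
#'   layers (and updates running statistics), `FALSE` uses running
#'   statistics.
#' @return list with `net` (updated caches/statistics) and `out`.
#' @export
networkForward <- function(net, x, train = FALSE) {
  for (i in seq_along(net$layers)) {
    r <- layerForward(net$layers[[i]], x, train)
    net$layers[[i]] <- r$layer
    x <- r$out
  }
  list(net = net, out = x)
}

netBackward <- function(net, dout) {
  for (i in rev(seq_along(net$layers))) {
    r <- layerBackward(net$layers[[i]], dout)
    net$layers[[i]] <- r$layer
    dout <- r$dx
  }
  list(net = net, dx = dout)
}

zeroGrads <- function(net) {
  for (i in seq_along(net$layers)) {
    l <- net$layers[[i]]
    for (p in l$params) l[[paste0("g", p)]] <- NULL
    net$layers[[i]] <- l
  }
  net
}

adamStep <- function(net, lr, beta1, beta2) {
  net$t <- net$t + 1L
  c1 <- 1 - beta1^net$t
  c2 <- 1 - beta2^net$t
  for (i in seq_along(net$layers)) {
    l <- net$layers[[i]]
    for (p in l$params) {
      g <- l[[paste0("g", p)]]
      if (is.null(g)) next
      mSlot <- paste0("m", p)
      vSlot <- paste0("v", p)
      if (is.null(l[[mSlot]])) {
        l[[mSlot]] <- numeric(length(g))
        l[[vSlot]] <- numeric(length(g))
      }
      ## fused in-place update (buffers are private to the training loop)
      .adamUpdate(l[[p]], g, l[[mSlot]], l[[vSlot]], lr, beta1, beta2,
                  c1, c2, ADAM_EPS)
    }
    net$layers[[i]] <- l
  }
  net
}

## drop activation caches and batch plans before storing a network
stripCaches <- function(net) {
  volatile <- c("x", "xhat", "invstd", "M", "y", "mask", "colB", "xB")
  for (i in seq_along(net$layers)) {
    l <- net$layers[[i]]
    for (s in volatile) l[[s]] <- NULL
    for (p in l$params) l[[paste0("g", p)]] <- NULL
    if (l$kind %in% c("conv", "tconv")) l$plans <- list()
    if (l$kind == "flatten") l$dims <- NULL   # dims is a cache here only
    net$layers[[i]] <- l
  }
  net
}

## extract all trainable parameters (for determinism checks)
netParameters <- function(net) {
  lapply(net$layers, function(l) l[l$params])
}
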