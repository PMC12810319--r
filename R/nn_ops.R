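# Network assembly on top of the C++ kernels: layer graph construction,
# forward/backward passes, adaptive average pooling, the dense head and the
# Adam optimizer. All tensors are (H, W, C, N) arrays.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

# evaluate expr under a temporary RNG state seeded with `seed`
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# ---- layer constructors (descriptors only; parameters live in a flat list)

.convLayer <- function(id, cin, cout, k, stride, pad) {
  list(type = "conv", id = id, cin = cin, cout = cout, k = k,
       stride = stride, pad = pad,
       w = paste0(id, ".w"), b = paste0(id, ".b"))
}

.bnLayer <- function(id, c) {
  list(type = "bn", id = id, c = c,
       gamma = paste0(id, ".g"), beta = paste0(id, ".b"),
       rmean = paste0(id, ".rm"), rvar = paste0(id, ".rv"))
}

.reluLayer <- function(id) list(type = "relu", id = id)

.bnreluLayer <- function(id, c) {
  l <- .bnLayer(id, c)
  l$type <- "bnrelu"
  l
}

.resBlock <- function(id, width) {
  list(type = "resblock", id = id,
       layers = list(
         .convLayer(paste0(id, ".c1"), width, width, 3L, 1L, 1L),
         .bnreluLayer(paste0(id, ".n1"), width),
         .convLayer(paste0(id, ".c2"), width, width, 3L, 1L, 1L),
         .bnLayer(paste0(id, ".n2"), width)
       ))
}

# downsampling device: two consecutive 2x2 stride-2 convolutions (in place of
# pooling); cmid lets the first conv of the pair run narrower than the target
.downsamplePair <- function(id, cin, cout, cmid = cout) {
  list(
    .convLayer(paste0(id, ".d1"), cin, cmid, 2L, 2L, 0L),
    .bnreluLayer(paste0(id, ".n1"), cmid),
    .convLayer(paste0(id, ".d2"), cmid, cout, 2L, 2L, 0L),
    .bnreluLayer(paste0(id, ".n2"), cout)
  )
}

# ---- parameter initialization

.initParams <- function(trunk, head, finalBiasInit = 0) {
  weights <- list()
  buffers <- list()
  initLayer <- function(l) {
    switch(l$type,
      conv = {
        fanIn <- l$k * l$k * l$cin
        weights[[l$w]] <<- array(rnorm(l$k * l$k * l$cin * l$cout,
                                       sd = sqrt(2 / fanIn)),
                                 dim = c(l$k, l$k, l$cin, l$cout))
        weights[[l$b]] <<- numeric(l$cout)
      },
      bn = ,
      bnrelu = {
        weights[[l$gamma]] <<- rep(1, l$c)
        weights[[l$beta]] <<- numeric(l$c)
        buffers[[l$rmean]] <<- numeric(l$c)
        buffers[[l$rvar]] <<- rep(1, l$c)
      },
      resblock = lapply(l$layers, initLayer),
      NULL)
    invisible(NULL)
  }
  lapply(trunk, initLayer)
  weights[["head.w1"]] <- matrix(rnorm(head$fc * head$inDim,
                                       sd = sqrt(2 / head$inDim)),
                                 head$fc, head$inDim)
  weights[["head.b1"]] <- numeric(head$fc)
  weights[["head.w2"]] <- matrix(rnorm(head$fc, sd = 0.01), 1L, head$fc)
  weights[["head.b2"]] <- finalBiasInit
  list(weights = weights, buffers = buffers)
}

# ---- forward / backward over the trunk

.layerForward <- function(l, x, weights, buffers, training) {
  switch(l$type,
    conv = {
      y <- cs_conv_fwd(x, weights[[l$w]], weights[[l$b]], l$stride, l$pad)
      list(y = y, cache = list(x = x), buffers = NULL)
    },
    bn = {
      if (training) {
        r <- cs_bn_fwd(x, weights[[l$gamma]], weights[[l$beta]], BN_EPS,
                       FALSE, numeric(l$c), numeric(l$c))
        M <- prod(dim(x)[c(1, 2, 4)])
        ub <- if (M > 1) r$var * M / (M - 1) else r$var
        upd <- list()
        upd[[l$rmean]] <- (1 - BN_MOMENTUM) * buffers[[l$rmean]] +
          BN_MOMENTUM * r$mean
        upd[[l$rvar]] <- (1 - BN_MOMENTUM) * buffers[[l$rvar]] +
          BN_MOMENTUM * ub
        list(y = r$y, cache = list(x = x, mean = r$mean, var = r$var),
             buffers = upd)
      } else {
        r <- cs_bn_fwd(x, weights[[l$gamma]], weights[[l$beta]], BN_EPS,
                       TRUE, buffers[[l$rmean]], buffers[[l$rvar]])
        list(y = r$y, cache = NULL, buffers = NULL)
      }
    },
    bnrelu = {
      if (training) {
        r <- cs_bnrelu_fwd(x, weights[[l$gamma]], weights[[l$beta]], BN_EPS,
                           FALSE, numeric(l$c), numeric(l$c))
        M <- prod(dim(x)[c(1, 2, 4)])
        ub <- if (M > 1) r$var * M / (M - 1) else r$var
        upd <- list()
        upd[[l$rmean]] <- (1 - BN_MOMENTUM) * buffers[[l$rmean]] +
          BN_MOMENTUM * r$mean
        upd[[l$rvar]] <- (1 - BN_MOMENTUM) * buffers[[l$rvar]] +
          BN_MOMENTUM * ub
        list(y = r$y, cache = list(x = x, mean = r$mean, var = r$var),
             buffers = upd)
      } else {
        r <- cs_bnrelu_fwd(x, weights[[l$gamma]], weights[[l$beta]], BN_EPS,
                           TRUE, buffers[[l$rmean]], buffers[[l$rvar]])
        list(y = r$y, cache = NULL, buffers = NULL)
      }
    },
    relu = {
      y <- cs_relu_fwd(x)
      list(y = y, cache = list(y = y), buffers = NULL)
    },
    resblock = {
      r <- .trunkForward(l$layers, x, weights, buffers, training)
      s <- r$y + x                      # identity skip
      y <- cs_relu_fwd(s)
      list(y = y, cache = list(inner = r$caches, y = y, bufUpd = r$bufUpd),
           buffers = r$bufUpd)
    },
    stop("unknown layer type ", l$type))
}

.trunkForward <- function(layers, x, weights, buffers, training) {
  caches <- vector("list", length(layers))
  bufUpd <- list()
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    r <- .layerForward(l, x, weights, buffers, training)
    x <- r$y
    caches[[i]] <- r$cache
    if (!is.null(r$buffers)) bufUpd[names(r$buffers)] <- r$buffers
  }
  list(y = x, caches = caches, bufUpd = bufUpd)
}

.layerBackward <- function(l, cache, gy, weights, grads) {
  switch(l$type,
    conv = {
      r <- cs_conv_bwd(cache$x, weights[[l$w]], gy, l$stride, l$pad)
      grads[[l$w]] <- r$gw
      grads[[l$b]] <- r$gb
      list(gx = r$gx, grads = grads)
    },
    bn = {
      r <- cs_bn_bwd(cache$x, gy, weights[[l$gamma]], cache$mean,
                     cache$var, BN_EPS)
      grads[[l$gamma]] <- r$ggamma
      grads[[l$beta]] <- r$gbeta
      list(gx = r$gx, grads = grads)
    },
    bnrelu = {
      r <- cs_bnrelu_bwd(cache$x, gy, weights[[l$gamma]], weights[[l$beta]],
                         cache$mean, cache$var, BN_EPS)
      grads[[l$gamma]] <- r$ggamma
      grads[[l$beta]] <- r$gbeta
      list(gx = r$gx, grads = grads)
    },
    relu = {
      list(gx = cs_relu_bwd(cache$y, gy), grads = grads)
    },
    resblock = {
      gs <- cs_relu_bwd(cache$y, gy)    # through the closing ReLU
      r <- .trunkBackward(l$layers, cache$inner, gs, weights, grads)
      list(gx = r$gx + gs, grads = r$grads)   # skip path adds gs
    },
    stop("unknown layer type ", l$type))
}

.trunkBackward <- function(layers, caches, gy, weights, grads) {
  for (i in rev(seq_along(layers))) {
    r <- .layerBackward(layers[[i]], caches[[i]], gy, weights, grads)
    gy <- r$gx
    grads <- r$grads
  }
  list(gx = gy, grads = grads)
}

# ---- adaptive average pooling to a fixed out x out map

.poolBins <- function(inSize, outSize) {
  lapply(seq_len(outSize) - 1L, function(i) {
    seq.int(floor(i * inSize / outSize) + 1L,
            ceiling((i + 1) * inSize / outSize))
  })
}

.adaptivePoolFwd <- function(x, outSize = 6L) {
  d <- dim(x)
  bins <- .poolBins(d[1], outSize)
  y <- array(0, dim = c(outSize, outSize, d[3], d[4]))
  for (i in seq_len(outSize)) {
    for (j in seq_len(outSize)) {
      blk <- x[bins[[i]], bins[[j]], , , drop = FALSE]
      y[i, j, , ] <- colMeans(matrix(blk,
                                     nrow = length(bins[[i]]) * length(bins[[j]])))
    }
  }
  y
}

.adaptivePoolBwd <- function(gy, inSize, outSize = 6L) {
  d <- dim(gy)
  bins <- .poolBins(inSize, outSize)
  gx <- array(0, dim = c(inSize, inSize, d[3], d[4]))
  for (i in seq_len(outSize)) {
    for (j in seq_len(outSize)) {
      cnt <- length(bins[[i]]) * length(bins[[j]])
      g <- gy[i, j, , ] / cnt
      for (bi in bins[[i]]) {
        for (bj in bins[[j]]) {
          gx[bi, bj, , ] <- gx[bi, bj, , ] + g
        }
      }
    }
  }
  gx
}

# ---- full network forward/backward (trunk + pool + metadata-fused head)

.netForward <- function(model, x, meta, training = FALSE) {
  weights <- model@params$weights
  buffers <- model@params$buffers
  tr <- .trunkForward(model@arch$trunk, x, weights, buffers, training)
  inSize <- dim(tr$y)[1]
  pooled <- .adaptivePoolFwd(tr$y, model@arch$poolSize)
  N <- dim(pooled)[4]
  flat <- matrix(pooled, nrow = prod(dim(pooled)[1:3]), ncol = N)
  feats <- rbind(flat, meta)
  a1 <- weights[["head.w1"]] %*% feats + weights[["head.b1"]]
  h1 <- pmax(a1, 0)
  out <- weights[["head.w2"]] %*% h1 + weights[["head.b2"]]
  list(pred = as.numeric(out),
       cache = list(trunk = tr$caches, trunkOut = tr$y, inSize = inSize,
                    flatDim = nrow(flat), feats = feats, h1 = h1),
       bufUpd = tr$bufUpd)
}

.netBackward <- function(model, cache, gpred) {
  weights <- model@params$weights
  grads <- list()
  g2 <- matrix(gpred, nrow = 1L)
  grads[["head.w2"]] <- g2 %*% t(cache$h1)
  grads[["head.b2"]] <- sum(g2)
  gh1 <- t(weights[["head.w2"]]) %*% g2
  gh1[cache$h1 <= 0] <- 0
  grads[["head.w1"]] <- gh1 %*% t(cache$feats)
  grads[["head.b1"]] <- rowSums(gh1)
  gfeats <- t(weights[["head.w1"]]) %*% gh1
  gflat <- gfeats[seq_len(cache$flatDim), , drop = FALSE]
  gmeta <- gfeats[cache$flatDim + seq_len(6L), , drop = FALSE]
  cLast <- cache$flatDim / model@arch$poolSize^2
  gpool <- array(gflat, dim = c(model@arch$poolSize, model@arch$poolSize,
                                cLast, ncol(gflat)))
  gtrunk <- .adaptivePoolBwd(gpool, cache$inSize, model@arch$poolSize)
  r <- .trunkBackward(model@arch$trunk, cache$trunk, gtrunk, weights, grads)
  list(grads = r$grads, gmeta = gmeta)
}

# ---- Adam (coupled L2 weight decay added to the gradient, as in the
#      standard deep-learning implementation)

.adamInit <- function(weights) {
  list(m = lapply(weights, function(w) w * 0),
       v = lapply(weights, function(w) w * 0),
       t = 0L)
}

.adamStep <- function(weights, grads, state, lr, weightDecay,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(weights)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    g <- g + weightDecay * weights[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    weights[[nm]] <- weights[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(weights = weights, state = state)
}
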