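# Numerical verification of the network kernels against naive R oracles
# and finite differences.

naiveConv <- function(x, w, b, stride, pad) {
  d <- dim(x); wd <- dim(w)
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  kh <- wd[1]; kw <- wd[2]; Cout <- wd[4]
  Hp <- H + 2 * pad
  Ho <- (Hp - kh) %/% stride + 1L
  y <- array(0, dim = c(Ho, Ho, Cout, N))
  xp <- array(0, dim = c(Hp, Hp, C, N))
  xp[pad + 1:H, pad + 1:W, , ] <- x
  for (n in 1:N) for (co in 1:Cout) for (oi in 1:Ho) for (oj in 1:Ho) {
    acc <- b[co]
    for (ci in 1:C) for (ki in 1:kh) for (kj in 1:kw) {
      acc <- acc + w[ki, kj, ci, co] *
        xp[(oi - 1) * stride + ki, (oj - 1) * stride + kj, ci, n]
    }
    y[oi, oj, co, n] <- acc
  }
  y
}

test_that("direct convolution matches a naive R oracle", {
  withSeed(41, {
    for (cfg in list(list(k = 3L, s = 1L, p = 1L), list(k = 2L, s = 2L, p = 0L))) {
      x <- array(rnorm(9 * 9 * 3 * 2), dim = c(9, 9, 3, 2))
      w <- array(rnorm(cfg$k * cfg$k * 3 * 4), dim = c(cfg$k, cfg$k, 3, 4))
      b <- rnorm(4)
      got <- cryosift:::cs_conv_fwd(x, w, b, cfg$s, cfg$p)
      want <- naiveConv(x, w, b, cfg$s, cfg$p)
      expect_equal(as.vector(got), as.vector(want), tolerance = 1e-12)
      expect_equal(dim(got), dim(want))
    }
  })
})

test_that("convolution backward matches finite differences", {
  withSeed(42, {
    x <- array(rnorm(6 * 6 * 2 * 2), dim = c(6, 6, 2, 2))
    w <- array(rnorm(3 * 3 * 2 * 3, sd = 0.5), dim = c(3, 3, 2, 3))
    b <- rnorm(3)
    gy <- array(rnorm(6 * 6 * 3 * 2), dim = c(6, 6, 3, 2))
    loss <- function(x, w, b) sum(cryosift:::cs_conv_fwd(x, w, b, 1L, 1L) * gy)
    bwd <- cryosift:::cs_conv_bwd(x, w, gy, 1L, 1L)
    eps <- 1e-6
    for (idx in c(1L, 17L, 40L)) {
      xp <- x; xp[idx] <- xp[idx] + eps
      xm <- x; xm[idx] <- xm[idx] - eps
      expect_equal(bwd$gx[idx], (loss(xp, w, b) - loss(xm, w, b)) / (2 * eps),
                   tolerance = 1e-5)
      wp <- w; wp[idx] <- wp[idx] + eps
      wm <- w; wm[idx] <- wm[idx] - eps
      expect_equal(bwd$gw[idx], (loss(x, wp, b) - loss(x, wm, b)) / (2 * eps),
                   tolerance = 1e-5)
    }
    bp <- b; bp[2] <- bp[2] + eps
    bm <- b; bm[2] <- bm[2] - eps
    expect_equal(bwd$gb[2], (loss(x, w, bp) - loss(x, w, bm)) / (2 * eps),
                 tolerance = 1e-5)
  })
})

test_that("batch norm normalizes per channel and its backward is exact", {
  withSeed(43, {
    x <- array(rnorm(5 * 5 * 3 * 4, mean = 2, sd = 3), dim = c(5, 5, 3, 4))
    g <- runif(3, 0.5, 2); be <- rnorm(3)
    r <- cryosift:::cs_bn_fwd(x, g, be, 1e-5, FALSE, numeric(3), numeric(3))
    for (c in 1:3) {
      slab <- x[, , c, ]
      expect_equal(r$mean[c], mean(slab), tolerance = 1e-12)
      expect_equal(r$var[c], mean((slab - mean(slab))^2), tolerance = 1e-12)
      ych <- r$y[, , c, ]
      expect_equal(mean(ych), be[c], tolerance = 1e-6)
      expect_equal(sd(as.vector(ych)) * sqrt((length(ych) - 1) / length(ych)),
                   g[c], tolerance = 1e-3)
    }
    gy <- array(rnorm(5 * 5 * 3 * 4), dim = c(5, 5, 3, 4))
    bwd <- cryosift:::cs_bn_bwd(x, gy, g, r$mean, r$var, 1e-5)
    loss <- function(x2) {
      sum(cryosift:::cs_bn_fwd(x2, g, be, 1e-5, FALSE, numeric(3),
                               numeric(3))$y * gy)
    }
    eps <- 1e-6
    for (idx in c(3L, 77L, 200L)) {
      xp <- x; xp[idx] <- xp[idx] + eps
      xm <- x; xm[idx] <- xm[idx] - eps
      expect_equal(bwd$gx[idx], (loss(xp) - loss(xm)) / (2 * eps),
                   tolerance = 1e-4)
    }
  })
})

test_that("fused bn+relu agrees with the separate kernels", {
  withSeed(44, {
    x <- array(rnorm(7 * 7 * 2 * 3), dim = c(7, 7, 2, 3))
    g <- runif(2, 0.5, 2); be <- rnorm(2)
    sep <- cryosift:::cs_bn_fwd(x, g, be, 1e-5, FALSE, numeric(2), numeric(2))
    fused <- cryosift:::cs_bnrelu_fwd(x, g, be, 1e-5, FALSE, numeric(2),
                                      numeric(2))
    expect_equal(as.vector(fused$y), pmax(as.vector(sep$y), 0),
                 tolerance = 1e-12)
    gy <- array(rnorm(length(x)), dim = dim(x))
    fbwd <- cryosift:::cs_bnrelu_bwd(x, gy, g, be, sep$mean, sep$var, 1e-5)
    gyMasked <- gy * (sep$y > 0)
    sbwd <- cryosift:::cs_bn_bwd(x, gyMasked, g, sep$mean, sep$var, 1e-5)
    expect_equal(as.vector(fbwd$gx), as.vector(sbwd$gx), tolerance = 1e-12)
    expect_equal(fbwd$ggamma, sbwd$ggamma, tolerance = 1e-12)
  })
})

test_that("adaptive pooling hits 6 x 6 for any trunk output size", {
  withSeed(45, {
    for (inSize in c(3L, 4L, 6L, 7L, 13L)) {
      x <- array(rnorm(inSize^2 * 2 * 2), dim = c(inSize, inSize, 2L, 2L))
      y <- cryosift:::.adaptivePoolFwd(x, 6L)
      expect_equal(dim(y), c(6L, 6L, 2L, 2L))
      # global mean is preserved for sizes that divide evenly
      if (inSize %% 6L == 0L || 6L %% inSize == 0L) {
        expect_equal(mean(y[, , 1, 1]), mean(x[, , 1, 1]), tolerance = 1e-12)
      }
      # backward distributes gradient: sums match for even partitions
      gy <- array(rnorm(6 * 6 * 2 * 2), dim = c(6L, 6L, 2L, 2L))
      gx <- cryosift:::.adaptivePoolBwd(gy, inSize, 6L)
      expect_equal(dim(gx), dim(x))
      if (inSize == 6L) expect_equal(gx, gy)
    }
  })
})

test_that("the assembled network gradient matches finite differences", {
  cfg <- tinyScorerConfig()
  model <- buildScorer(cfg)
  withSeed(46, {
    x <- array(rnorm(210 * 210 * 2, sd = 0.5), dim = c(210, 210, 1, 2))
    meta <- matrix(rnorm(12), 6, 2)
    target <- c(2, 4)
    lossAt <- function(m) {
      p <- cryosift:::.netForward(m, x, meta, training = TRUE)$pred
      sum((p - target)^2)
    }
    fw <- cryosift:::.netForward(model, x, meta, training = TRUE)
    bw <- cryosift:::.netBackward(model, fw$cache, 2 * (fw$pred - target))
    eps <- 1e-5
    for (nm in c("stem.w", "s1b1.c1.w", "head.w1", "head.w2", "stem.n.g")) {
      wv <- model@params$weights[[nm]]
      idx <- min(3L, length(wv))
      mp <- model; mp@params$weights[[nm]][idx] <- wv[idx] + eps
      mm <- model; mm@params$weights[[nm]][idx] <- wv[idx] - eps
      num <- (lossAt(mp) - lossAt(mm)) / (2 * eps)
      # finite differences cross ReLU kinks; a 2% agreement is the check
      expect_equal(bw$grads[[nm]][idx], num, tolerance = 2e-2,
                   label = paste("grad", nm))
    }
  })
})
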