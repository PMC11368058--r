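# The conv-net engine is validated against finite differences and naive
# references; every trainable stage rests on these primitives.

test_that("convolution forward matches a naive loop incl. stride/pad/dilation", {
  set.seed(1)
  x <- array(rnorm(9 * 8), c(9, 8, 1, 1))
  W <- array(rnorm(9), c(3, 3, 1, 1))
  fw <- pseudohealthy:::.convForward(x, W, b = 0.3, stride = 2L, pad = 1L,
                                     dilation = 1L)
  xp <- matrix(0, 11, 10); xp[2:10, 2:9] <- x[, , 1, 1]
  Ho <- dim(fw$out)[1]; Wo <- dim(fw$out)[2]
  ref <- matrix(0, Ho, Wo)
  for (i in seq_len(Ho)) for (j in seq_len(Wo)) {
    acc <- 0.3
    for (a in 0:2) for (b in 0:2)
      acc <- acc + xp[(i - 1) * 2 + 1 + a, (j - 1) * 2 + 1 + b] *
        W[a + 1, b + 1, 1, 1]
    ref[i, j] <- acc
  }
  expect_equal(fw$out[, , 1, 1], ref, tolerance = 1e-12)
  # dilation widens the receptive field per the standard conv arithmetic
  fd <- pseudohealthy:::.convForward(x, W, stride = 1L, pad = 2L,
                                     dilation = 2L)
  expect_equal(dim(fd$out)[1:2], c(9L, 8L)) # (H + 2*2 - 2*(3-1) - 1) + 1
})

test_that("convolution gradients agree with finite differences", {
  set.seed(2)
  x <- array(rnorm(7 * 6 * 3 * 2), c(7, 6, 3, 2))
  W <- array(rnorm(3 * 3 * 3 * 4, sd = 0.3), c(3, 3, 3, 4))
  b <- rnorm(4)
  fw <- pseudohealthy:::.convForward(x, W, b, stride = 2L, pad = 1L)
  R <- array(rnorm(length(fw$out)), dim(fw$out))
  bk <- pseudohealthy:::.convBackward(R, fw$cache)
  lossAt <- function(xx, WW, bb)
    sum(pseudohealthy:::.convForward(xx, WW, bb, 2L, 1L,
                                     needCache = FALSE)$out * R)
  e <- 1e-5
  for (i in sample(length(W), 4)) {
    Wp <- W; Wp[i] <- W[i] + e
    Wm <- W; Wm[i] <- W[i] - e
    expect_equal(bk$dW[i], (lossAt(x, Wp, b) - lossAt(x, Wm, b)) / (2 * e),
                 tolerance = 1e-5)
  }
  for (i in sample(length(x), 4)) {
    xp <- x; xp[i] <- x[i] + e
    xm <- x; xm[i] <- x[i] - e
    expect_equal(bk$dx[i], (lossAt(xp, W, b) - lossAt(xm, W, b)) / (2 * e),
                 tolerance = 1e-5)
  }
  for (i in seq_along(b)) {
    bp <- b; bp[i] <- b[i] + e
    bm <- b; bm[i] <- b[i] - e
    expect_equal(bk$db[i], (lossAt(x, W, bp) - lossAt(x, W, bm)) / (2 * e),
                 tolerance = 1e-5)
  }
})

test_that("max pooling and nearest upsampling invert shapes and route gradients", {
  set.seed(3)
  x <- array(rnorm(6 * 4 * 2 * 2), c(6, 4, 2, 2))
  mp <- pseudohealthy:::.maxPool2Forward(x)
  ref <- array(0, c(3, 2, 2, 2))
  for (i in 1:3) for (j in 1:2) for (c in 1:2) for (n in 1:2)
    ref[i, j, c, n] <- max(x[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j), c, n])
  expect_equal(mp$out, ref)
  d <- array(rnorm(length(mp$out)), dim(mp$out))
  bk <- pseudohealthy:::.maxPool2Backward(d, mp$cache)
  # gradient mass is conserved and lands on argmax positions only
  expect_equal(sum(bk), sum(d))
  expect_equal(sum(bk != 0), length(d))
  u <- pseudohealthy:::.upsample2Forward(x)
  expect_equal(dim(u), c(12L, 8L, 2L, 2L))
  expect_equal(u[2, 2, 1, 1], x[1, 1, 1, 1])
  du <- array(rnorm(length(u)), dim(u))
  bu <- pseudohealthy:::.upsample2Backward(du)
  expect_equal(bu[1, 1, 1, 1], sum(du[1:2, 1:2, 1, 1]))
})

test_that("Adam leaves parameters untouched at zero learning rate and moves them otherwise", {
  set.seed(4)
  p <- list(a = matrix(rnorm(4), 2), b = rnorm(3))
  g <- list(a = matrix(rnorm(4), 2), b = rnorm(3))
  st <- pseudohealthy:::.adamInit(p)
  up0 <- pseudohealthy:::.adamStep(p, g, st, lr = 0)
  expect_identical(up0$params, p)
  up1 <- pseudohealthy:::.adamStep(p, g, st, lr = 1e-2)
  expect_gt(max(abs(up1$params$a - p$a)), 0)
})
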