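test_that("intensity normalization maps extremes linearly and handles degenerate input", {
  raw <- matrix(c(0, 127.5, 255, 64), 2, 2)
  s <- normalizeIntensity(raw)
  expect_equal(pixels(s)[1, 1], -1)
  expect_equal(pixels(s)[1, 2], 1)
  expect_equal(pixels(s)[2, 1], 0)
  # two-point map
  s2 <- normalizeIntensity(matrix(c(-3, 1), 1, 2))
  expect_equal(as.vector(pixels(s2)), c(-1, 1))
  # constant input: all background
  s3 <- normalizeIntensity(matrix(7, 3, 3))
  expect_true(all(pixels(s3) == -1))
  # non-finite input rejected
  expect_error(normalizeIntensity(matrix(c(1, NA), 1, 2)), "finite")
})

test_that("normalization is affine, order-preserving and idempotent", {
  set.seed(4)
  raw <- matrix(rnorm(100, 50, 20), 10, 10)
  s <- normalizeIntensity(raw)
  expect_equal(order(as.vector(raw)), order(as.vector(pixels(s))))
  # applying twice equals applying once
  s2 <- normalizeIntensity(pixels(s))
  expect_equal(pixels(s2), pixels(s), tolerance = 1e-12)
})

test_that("horizontal flip is an involution about the vertical midline", {
  m <- matrix(c(1, 3, 2, 4), 2, 2) # [[1,2],[3,4]] row-wise
  expect_equal(horizontalFlip(m), matrix(c(2, 4, 1, 3), 2, 2))
  s <- randomSlice(17, 23, seed = 9)
  expect_equal(pixels(horizontalFlip(horizontalFlip(s))), pixels(s))
  sym <- makeHealthyPhantom(phantomSpec(size = 32, noiseSigma = 0, seed = 2))
  expect_identical(pixels(horizontalFlip(sym)), pixels(sym))
})

test_that("mask dilation uses the exact Euclidean disk in millimetres", {
  m <- matrix(0, 21, 21); m[11, 11] <- 1
  d0 <- dilateMask(LesionMask(m), 0)
  expect_equal(pixels(d0), pixels(LesionMask(m)))
  d5 <- dilateMask(LesionMask(m, spacing = 1), 5)
  # lattice points with dx^2 + dy^2 <= 25
  expect_equal(sum(pixels(d5)), 81)
  # spacing scales the pixel radius: 5 mm at 2.5 mm spacing = 2 px disk
  d2 <- dilateMask(LesionMask(m, spacing = 2.5), 5)
  expect_equal(sum(pixels(d2)), sum(outer((-2):2, (-2):2,
                                          function(a, b) a^2 + b^2) <= 4))
  ones <- LesionMask(matrix(1, 9, 9))
  expect_equal(pixels(dilateMask(ones, 3)), pixels(ones))
  expect_error(dilateMask(ones, -1), "nonnegative")
})

test_that("mask dilation is monotone and extensive on random masks", {
  set.seed(11)
  for (i in 1:5) {
    a <- matrix(rbinom(400, 1, 0.08), 20, 20)
    extra <- matrix(rbinom(400, 1, 0.05), 20, 20)
    b <- pmax(a, extra) # a subset of b
    da <- pixels(dilateMask(LesionMask(a), 2))
    db <- pixels(dilateMask(LesionMask(b), 2))
    expect_true(all(da >= a))           # extensive
    expect_true(all(db >= da))          # monotone
  }
})

test_that("compositing preserves the original outside the mask bit-exactly", {
  orig <- randomSlice(16, seed = 1)
  gen <- randomSlice(16, seed = 2)
  m0 <- LesionMask(matrix(0, 16, 16))
  m1 <- LesionMask(matrix(1, 16, 16))
  expect_identical(pixels(compositeSlice(orig, gen, m0)), pixels(orig))
  expect_identical(pixels(compositeSlice(orig, gen, m1)), pixels(gen))
  set.seed(3)
  m <- LesionMask(matrix(rbinom(256, 1, 0.4), 16, 16))
  out <- compositeSlice(orig, gen, m)
  sel <- pixels(m) == 0
  expect_identical(pixels(out)[sel], pixels(orig)[sel])
  expect_identical(pixels(out)[!sel], pixels(gen)[!sel])
  expect_equal(maskedPSNR(out, orig, m), 99)
  expect_error(compositeSlice(orig, randomSlice(8), m), "shape")
})

test_that("patch extraction tiles exactly and scatters back to the input", {
  set.seed(6)
  f <- array(rnorm(32 * 32 * 3), c(32, 32, 3))
  m <- matrix(0, 32, 32); m[1:10, 1:4] <- 1
  ps <- extractPatches(f, 16, m)
  expect_equal(ncol(ps@patches), 4L)
  expect_equal(sum(ps@inside), 1L) # only the top-left patch touches the mask
  expect_equal(scatterPatches(ps, drop = FALSE), f)
  # divisibility is enforced
  expect_error(extractPatches(matrix(0, 250, 250), 16, matrix(0, 250, 250)),
               "divisible")
  # inside rule: any masked pixel marks the patch inside
  m2 <- matrix(0, 32, 32); m2[17, 32] <- 1
  ps2 <- extractPatches(f, 16, m2)
  expect_equal(which(ps2@inside), 4L) # raster order: bottom-right patch
  expect_equal(nOutside(ps2), 3L)
})
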