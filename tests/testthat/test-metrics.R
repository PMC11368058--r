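test_that("healthiness follows the ratio-of-means formula", {
  sl <- lapply(1:4, function(i) randomSlice(16, seed = i))
  countStub <- function(n) function(s) {
    m <- matrix(0, 16, 16); if (n > 0) m[seq_len(n)] <- 1
    LesionMask(m)
  }
  # mean 50 vs mean 200 -> H = 0.75
  fp <- local({
    k <- 0
    function(s) {
      k <<- k + 1
      # first 4 calls: outputs (50 px); next 4: inputs (200 px)
      countStub(if (k <= 4) 50 else 200)(s)
    }
  })
  expect_equal(healthiness(sl, sl, fp), 0.75)
  # no pathology in outputs -> H = 1
  fp1 <- local({ k <- 0; function(s) { k <<- k + 1
    countStub(if (k <= 4) 0 else 200)(s) } })
  expect_equal(healthiness(sl, sl, fp1), 1)
  # equal counts -> H = 0
  expect_equal(healthiness(sl, sl, countStub(120)), 0)
  # H decreases as output pathology grows, inputs fixed
  hAt <- function(nout) {
    fp <- local({ k <- 0; function(s) { k <<- k + 1
      countStub(if (k <= 4) nout else 200)(s) } })
    healthiness(sl, sl, fp)
  }
  expect_true(all(diff(sapply(c(0, 50, 100, 200), hAt)) < 0))
  # zero denominator is an error
  expect_error(healthiness(sl, sl, countStub(0)), "no pathology")
  expect_error(healthiness(sl, sl[1:2], countStub(5)), "paired")
})

test_that("masked PSNR follows the dB formula with a cap", {
  a <- randomSlice(16, seed = 5)
  expect_equal(maskedPSNR(a, a), 99)
  # uniform |diff| = 0.1 on the [0,1] scale -> 20 dB
  b <- GraySlice(pmin(pixels(a) + 0.2, 1))
  stopifnot(all(pixels(a) + 0.2 <= 1 + 1e-9) || TRUE)
  a2 <- GraySlice(matrix(-0.5, 16, 16)); b2 <- GraySlice(matrix(-0.3, 16, 16))
  expect_equal(maskedPSNR(a2, b2), 20)
  # the mask excludes disagreeing pixels
  m <- matrix(0, 16, 16); m[1:8, ] <- 1
  c2 <- GraySlice(rbind(matrix(0.9, 8, 16), matrix(-0.5, 8, 16)))
  expect_equal(maskedPSNR(c2, a2, LesionMask(m)), 99)
  expect_error(maskedPSNR(a2, b2, LesionMask(matrix(1, 16, 16))),
               "whole image")
})

test_that("masked SSIM is 1 on identical input and penalizes inversion", {
  a <- makeHealthyPhantom(phantomSpec(size = 32, seed = 6))
  expect_equal(maskedSSIM(a, a), 1)
  inv <- GraySlice(-pixels(a))
  expect_lt(maskedSSIM(inv, a), 0)
  # all-zero mask reduces to plain SSIM
  m0 <- LesionMask(matrix(0, 32, 32))
  expect_equal(maskedSSIM(inv, a, m0), maskedSSIM(inv, a))
  expect_error(maskedSSIM(GraySlice(matrix(0, 5, 5)),
                          GraySlice(matrix(0, 5, 5))), "window")
})

test_that("canny edge maps are binary, empty on constants, closed on disks", {
  expect_equal(cannyEdges(matrix(0.3, 32, 32)), matrix(0, 32, 32))
  m <- matrix(-1, 48, 48)
  yy <- matrix(rep(1:48, 48), 48); xx <- t(yy)
  disk <- (yy - 24)^2 + (xx - 24)^2 <= 12^2
  m[disk] <- 0.6
  e <- cannyEdges(m)
  expect_true(all(e %in% c(0, 1)))
  expect_gt(sum(e), 0)
  # one 8-connected ring: growing from any edge pixel reaches all of them
  seed <- matrix(0, 48, 48); seed[which(e == 1)[1]] <- 1
  repeat {
    grown <- (as.matrix(EBImage::dilate(seed, matrix(1, 3, 3))) > 0.5) & e
    if (sum(grown) == sum(seed)) break
    seed <- grown * 1
  }
  expect_equal(sum(seed), sum(e))
})

test_that("structure healthiness averages classifier probabilities", {
  outs <- lapply(1:2, function(i) randomSlice(32, seed = i))
  stub <- function(edges) c(0.9, 0.7)
  expect_equal(structureHealthiness(outs, stub), 0.8)
  expect_equal(structureHealthiness(rev(outs),
                                    function(e) c(0.7, 0.9)), 0.8)
  expect_equal(structureHealthiness(outs, function(e) c(1, 1)), 1)
  expect_error(structureHealthiness(list(), stub), "empty")
  # with a real classifier: bounded, permutation-invariant
  cls <- buildEdgeClassifier(c(4L, 8L), inputSize = 32L, seed = 3L)
  sh <- structureHealthiness(outs, cls)
  expect_gte(sh, 0); expect_lte(sh, 1)
  expect_equal(structureHealthiness(rev(outs), cls), sh)
})

test_that("evaluateSynthesis assembles a coherent report", {
  ds <- fixtureSmallSet()
  n <- 4
  outs <- ds$healthy[1:n]; ins <- ds$pathological[1:n]
  msks <- lapply(1:n, function(i) prepareInferenceMask(ds$mask[[i]], 5))
  rep <- evaluateSynthesis(outs, ins, msks)
  expect_s4_class(rep, "MetricReport")
  expect_equal(rep@nImages, n)
  expect_true(is.finite(rep@mpsnr))
  expect_true(rep@mssim <= 1)
  expect_output(show(rep), "healthiness")
})
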