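test_that("gated convolutions saturate to plain conv or zero at extreme gate bias", {
  set.seed(7)
  V <- buildVagueFiller(c(4L, 4L, 4L), dilations = 1L, seed = 2L)
  x <- array(rnorm(16 * 16 * 2 * 1), c(16, 16, 2, 1))
  p <- V@params
  # gate bias >> 0: sigmoid ~ 1, output ~ ELU(conv_feature)
  p[["g1.bg"]][] <- 50
  g <- pseudohealthy:::.gconvForward(x, p, "g1", stride = 2L, pad = 2L)
  cf <- pseudohealthy:::.convForward(x, p[["g1.Wf"]], p[["g1.bf"]],
                                     stride = 2L, pad = 2L)
  expect_lt(max(abs(g$out - pseudohealthy:::.eluF(cf$out))), 1e-8)
  # gate bias << 0: output ~ 0
  p[["g1.bg"]][] <- -50
  g0 <- pseudohealthy:::.gconvForward(x, p, "g1", stride = 2L, pad = 2L)
  expect_lt(max(abs(g0$out)), 1e-8)
})

test_that("the coarse filler maps H x W to H x W deterministically", {
  ds <- fixtureSmallSet()
  V <- asTrained(buildVagueFiller(c(4L, 8L, 8L), seed = 3L))
  img <- ds$healthy[[1]]
  fg <- pixels(img) > -1 + 1e-9
  m <- sampleTrainingMask(c(64, 64), fg, seed = 5)
  out1 <- vagueFill(V, img, m)
  out2 <- vagueFill(V, img, m)
  expect_equal(dim(pixels(out1)), dim(pixels(img)))
  expect_identical(pixels(out1), pixels(out2)) # bit-identical repeat
  expect_true(all(abs(pixels(out1)) <= 1))
  expect_error(vagueFill(V, img, LesionMask(matrix(0, 32, 32))), "shape")
  expect_error(vagueFill(V, GraySlice(matrix(0, 30, 30)),
                         LesionMask(matrix(0, 30, 30))), "divisible")
})

test_that("the filler never reads masked pixels of the original image", {
  ds <- fixtureSmallSet()
  V <- asTrained(buildVagueFiller(c(4L, 8L, 8L), seed = 3L))
  img <- ds$healthy[[2]]
  fg <- pixels(img) > -1 + 1e-9
  m <- sampleTrainingMask(c(64, 64), fg, seed = 6)
  out <- vagueFill(V, img, m)
  # perturb the original inside the mask: output must be unchanged
  px <- pixels(img)
  sel <- pixels(m) == 1
  px[sel] <- -px[sel] * 0.5
  out2 <- vagueFill(V, GraySlice(px, spacing(img)), m)
  expect_identical(pixels(out), pixels(out2))
})

test_that("l1 loss follows its arithmetic and symmetry contracts", {
  a <- GraySlice(matrix(0.2, 4, 4))
  expect_equal(l1Loss(a, a), 0)
  b <- GraySlice(matrix(0.7, 4, 4))
  expect_equal(l1Loss(a, b), 0.5)
  expect_equal(l1Loss(b, a), 0.5) # symmetric
  expect_equal(l1Loss(matrix(c(0, 1), 1), matrix(c(1, 1), 1)), 0.5)
  expect_error(l1Loss(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")
})

test_that("the learning-rate schedule halves every 5 epochs", {
  expect_equal(lrSchedule(0.001, 0), 0.001)
  expect_equal(lrSchedule(0.001, 4), 0.001)
  expect_equal(lrSchedule(0.001, 5), 0.0005)
  expect_equal(lrSchedule(0.001, 10), 0.00025)
})

test_that("training with zero learning rate leaves parameters unchanged", {
  ds <- fixtureSmallSet()
  V <- buildVagueFiller(c(4L, 8L, 8L), seed = 4L)
  tr <- trainVagueFiller(V, ds$healthy[1:4],
                         list(steps = 3L, batch = 2L, lr = 0, seed = 1L))
  expect_identical(tr$model@params, V@params)
  expect_length(tr$history, 3L)
  expect_error(trainVagueFiller(V, list()), "no training slices")
})

test_that("a short training run reduces the reconstruction loss trend", {
  ds <- fixtureSmallSet()
  V <- buildVagueFiller(c(4L, 8L, 8L), seed = 5L)
  tr <- trainVagueFiller(V, ds$healthy,
                         list(steps = 40L, batch = 4L, seed = 2L))
  expect_lt(mean(tail(tr$history, 5)), mean(head(tr$history, 5)))
})
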