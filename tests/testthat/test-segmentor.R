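test_that("the U-Net overfits a single pair (training-sanity oracle)", {
  ds <- fixtureSmallSet()
  img <- ds$pathological[[1]]
  msk <- ds$mask[[1]]
  model <- trainUnet(list(img), list(msk),
                     list(epochs = 200L, batch = 1L, baseWidth = 8L,
                          depth = 2L, seed = 3L, valFraction = 0,
                          lrHalveEvery = 100L))
  d <- diceScore(predictLesionMask(model, img), msk)
  expect_gt(d, 0.95)
})

test_that("segmentor training validates its inputs", {
  ds <- fixtureSmallSet()
  expect_error(trainUnet(list(), list()), "at least one")
  expect_error(trainUnet(ds$pathological[1:3], ds$mask[1:2]), "paired")
  empty <- lapply(1:3, function(i) LesionMask(matrix(0, 64, 64)))
  expect_error(trainUnet(ds$pathological[1:3], empty), "empty")
})

test_that("predicted masks are binary, shape-preserving, thresholded maps", {
  ds <- fixtureSmallSet()
  model <- buildUnet(4L, 2L, seed = 5L) # untrained is fine for contracts
  pm <- predictLesionMask(model, ds$pathological[[1]])
  expect_s4_class(pm, "LesionMask")
  expect_equal(dim(pixels(pm)), c(64L, 64L))
  expect_true(all(pixels(pm) %in% c(0, 1)))
  # non-divisible input sizes are resized through and back
  odd <- GraySlice(pixels(ds$pathological[[1]])[1:63, 1:61])
  pm2 <- predictLesionMask(model, odd)
  expect_equal(dim(pixels(pm2)), c(63L, 61L))
  # decision threshold semantics on the sigmoid map
  expect_true(validObject(model))
  expect_error(new("SegmentorModel", params = list(), config = list(),
                   threshold = 1.5), "threshold")
})

test_that("inference masks carry the 5 mm margin and contain the raw mask", {
  m <- matrix(0, 21, 21); m[11, 11] <- 1
  raw <- LesionMask(m, spacing = 1)
  expect_identical(pixels(prepareInferenceMask(raw, 0)), pixels(raw))
  d <- prepareInferenceMask(raw, 5)
  expect_equal(sum(pixels(d)), 81)
  expect_true(all(pixels(d) >= pixels(raw)))
  emp <- LesionMask(matrix(0, 8, 8))
  expect_equal(sum(pixels(prepareInferenceMask(emp, 5))), 0)
})

test_that("manual annotations collapse labels and respect shape contracts", {
  tmp <- tempfile(fileext = ".png")
  lab <- matrix(0, 20, 20)
  lab[3:6, 3:6] <- 1 / 255; lab[10:12, 10:12] <- 4 / 255 # labels {1, 4}
  png::writePNG(lab, tmp)
  m <- loadManualAnnotation(tmp)
  expect_true(all(pixels(m) %in% c(0, 1)))
  expect_equal(sum(pixels(m)), 16 + 9)
  # blank annotation -> empty mask
  png::writePNG(matrix(0, 20, 20), tmp)
  expect_equal(sum(pixels(loadManualAnnotation(tmp))), 0)
  # resize disabled: mismatch errors
  png::writePNG(lab, tmp)
  expect_error(loadManualAnnotation(tmp, targetShape = c(40, 40),
                                    resize = FALSE), "does not match")
  m2 <- loadManualAnnotation(tmp, targetShape = c(40, 40))
  expect_equal(dim(pixels(m2)), c(40L, 40L))
})

test_that("checkpoints round-trip models through a single-file archive", {
  model <- buildUnet(4L, 2L, seed = 6L)
  f <- tempfile(fileext = ".rds")
  saveCheckpoint(model, f)
  back <- loadCheckpoint(f)
  expect_s4_class(back, "SegmentorModel")
  expect_equal(back@params, model@params)
  expect_equal(back@threshold, model@threshold)
  ds <- fixtureSmallSet()
  expect_identical(pixels(predictLesionMask(back, ds$pathological[[1]])),
                   pixels(predictLesionMask(model, ds$pathological[[1]])))
})
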