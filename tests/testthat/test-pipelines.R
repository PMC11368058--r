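test_that("slice extraction strides deterministically from index zero", {
  set.seed(9)
  vol <- array(runif(8 * 8 * 155), c(8, 8, 155))
  sl <- extractSlices(vol, 5, keep = NULL)
  expect_length(sl, 31)
  expect_length(extractSlices(vol[, , 1:10], 1, keep = NULL), 10)
  sl2 <- extractSlices(vol[, , 1:10], 2, keep = NULL)
  expect_length(sl2, 5) # 0-based indices 0,2,4,6,8
  expect_equal(pixels(sl2[[2]]),
               pixels(normalizeIntensity(vol[, , 3])))
  expect_error(extractSlices(array(0, c(4, 4, 0)), 1), "empty")
  # default predicate drops near-empty slices
  vol2 <- array(-1, c(16, 16, 4)); vol2[, , 2] <- 1; vol2[1, 1, 3] <- 1
  sl3 <- extractSlices(lapply(1:4, function(k)
    GraySlice(vol2[, , k])), 1)
  expect_length(sl3, 1)
})

test_that("the large-lesion filter applies the strict 20% brain-area rule", {
  fg <- matrix(1, 10, 10) # brain area 100
  mk <- function(n) { m <- matrix(0, 10, 10); if (n > 0) m[seq_len(n)] <- 1
    LesionMask(m) }
  masks <- list(mk(21), mk(20), mk(0), mk(35))
  keep <- largeLesionFilter(masks, rep(list(fg), 4))
  expect_equal(keep, c(1L, 4L)) # 21% kept, exactly 20% excluded
  expect_error(largeLesionFilter(list(mk(5)), list(matrix(0, 10, 10))),
               "zero brain area")
  expect_error(largeLesionFilter(masks, rep(list(fg), 3)), "paired")
})

test_that("batch size defaults depend on the slice geometry", {
  expect_equal(defaultBatchSize(c(240, 240)), 16L)
  expect_equal(defaultBatchSize(c(256, 256)), 16L)
  expect_equal(defaultBatchSize(c(512, 512)), 4L)
})

test_that("training refuses pathological data and empty inputs", {
  ds <- fixtureSmallSet()
  expect_error(trainPseudoHealthy(list()), "no training slices")
  expect_error(trainPseudoHealthy(ds$pathological[1:2],
                                  gtMasks = ds$mask[1:2]),
               "healthy images only")
  # all-empty ground-truth masks are fine (the data is healthy)
  empty <- lapply(1:2, function(i) LesionMask(matrix(0, 64, 64)))
  tr <- trainPseudoHealthy(ds$healthy[1:2],
                           list(stepsV = 1L, stepsG = 1L, batch = 1L,
                                fillerWidths = c(4L, 4L, 4L), genWidth = 4L,
                                discWidth = 4L, patchSize = 8L, seed = 1L),
                           gtMasks = empty)
  expect_s4_class(tr$V, "VagueFillerModel")
  expect_s4_class(tr$G, "GeneratorModel")
  expect_s4_class(tr$D, "DiscriminatorModel")
  expect_true(all(c("l1", "d_loss", "g_adv", "perceptual", "total") %in%
                  names(tr$history)))
})

test_that("end-to-end training is deterministic under a fixed seed", {
  ds <- fixtureSmallSet()
  cfg <- list(stepsV = 3L, stepsG = 3L, batch = 2L,
              fillerWidths = c(4L, 4L, 4L), genWidth = 4L, discWidth = 4L,
              patchSize = 8L, seed = 7L)
  t1 <- trainPseudoHealthy(ds$healthy[1:6], cfg)
  t2 <- trainPseudoHealthy(ds$healthy[1:6], cfg)
  expect_identical(t1$history, t2$history)
  expect_identical(t1$G@params, t2$G@params)
  expect_identical(t1$V@params, t2$V@params)
})

test_that("synthesis preserves identity bit-exactly outside the dilated mask", {
  ds <- fixtureSmallSet()
  V <- asTrained(buildVagueFiller(c(4L, 8L, 8L), seed = 3L))
  G <- asTrained(buildGenerator(4L, 8L, TRUE, TRUE, seed = 4L))
  p <- ds$pathological[[1]]
  res <- synthesizePseudoHealthy(p, ds$mask[[1]], V, G)
  sel <- pixels(res$mask) == 0
  expect_identical(pixels(res$image)[sel], pixels(p)[sel])
  # the used mask is the 5 mm dilation of the provided annotation
  expect_identical(pixels(res$mask),
                   pixels(prepareInferenceMask(ds$mask[[1]], 5)))
  expect_equal(maskedPSNR(res$image, p, res$mask), 99)
  expect_equal(maskedSSIM(res$image, p, res$mask), 1)
  # empty mask: the input comes back unchanged
  res0 <- synthesizePseudoHealthy(p, LesionMask(matrix(0, 64, 64)), V, G)
  expect_identical(pixels(res0$image), pixels(p))
  # untrained models are rejected
  expect_error(synthesizePseudoHealthy(p, ds$mask[[1]],
                                       buildVagueFiller(c(4L, 4L, 4L)), G),
               "trained")
})

test_that("a full-image mask yields an entirely generated slice", {
  ds <- fixtureSmallSet()
  V <- asTrained(buildVagueFiller(c(4L, 8L, 8L), seed = 5L))
  G <- asTrained(buildGenerator(4L, 8L, TRUE, TRUE, seed = 6L))
  p <- ds$pathological[[2]]
  full <- LesionMask(matrix(1, 64, 64))
  res <- synthesizePseudoHealthy(p, full, V, G)
  expect_true(all(is.finite(pixels(res$image))))
  expect_equal(sum(pixels(res$mask)), 64 * 64)
})
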