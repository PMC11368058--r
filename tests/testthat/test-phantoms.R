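test_that("healthy phantoms are deterministic and symmetric without noise", {
  sp <- phantomSpec(size = 48, noiseSigma = 0, seed = 31)
  a <- makeHealthyPhantom(sp)
  b <- makeHealthyPhantom(sp)
  expect_identical(pixels(a), pixels(b))
  expect_identical(pixels(a), pixels(horizontalFlip(a)))
  # with noise the sides differ but the construction stays deterministic
  spn <- phantomSpec(size = 48, noiseSigma = 0.05, seed = 31)
  c1 <- makeHealthyPhantom(spn)
  expect_identical(pixels(c1), pixels(makeHealthyPhantom(spn)))
  expect_gt(max(abs(pixels(c1) - pixels(horizontalFlip(c1)))), 0)
})

test_that("phantom background count respects the analytic ellipse area bound", {
  sp <- phantomSpec(size = 64, seed = 5)
  ph <- makeHealthyPhantom(sp)
  ab <- sp@foregroundAxes
  nBackground <- sum(pixels(ph) == -1)
  # every foreground lattice point lies in the ellipse, so the count is at
  # most the area of the ellipse dilated by half a pixel diagonal
  expect_gte(nBackground,
             64^2 - pi * (ab[1L] + sqrt(0.5)) * (ab[2L] + sqrt(0.5)))
})

test_that("lesion injection is local, disk-shaped and validated", {
  ph <- makeHealthyPhantom(phantomSpec(size = 64, seed = 8))
  # no deformation, no shift: image unchanged, mask is the disk
  ls0 <- lesionSpec(c(32, 40), radius = 6, intensityShift = 0,
                    deformationAmplitude = 0)
  r0 <- injectLesion(ph, ls0)
  expect_identical(pixels(r0$image), pixels(ph))
  # lattice-disk area
  npx <- sum(outer((-6):6, (-6):6, function(a, b) a^2 + b^2) <= 36)
  expect_equal(sum(pixels(r0$mask)), npx)
  # with mass effect, changes stay within the amplitude-dilated disk
  ls <- lesionSpec(c(32, 40), radius = 6, intensityShift = 0.7,
                   deformationAmplitude = 3)
  r <- injectLesion(ph, ls)
  changed <- abs(pixels(r$image) - pixels(ph)) > 1e-12
  # locality: nothing beyond radius + amplitude from the centre moves
  yy <- matrix(rep(1:64, times = 64), 64); xx <- matrix(rep(1:64, each = 64), 64)
  rr <- sqrt((yy - 32)^2 + (xx - 40)^2)
  expect_true(all(!changed | rr < 6 + 3 + 1e-9))
  expect_gt(sum(changed & !(pixels(r$mask) == 1)), 0) # deforms surroundings
  # a lesion fully outside the foreground is rejected
  expect_error(injectLesion(ph, lesionSpec(c(2, 2), radius = 1)),
               "outside the foreground")
})

test_that("training masks land in the requested foreground fraction", {
  ph <- makeHealthyPhantom(phantomSpec(size = 64, noiseSigma = 0, seed = 3))
  fg <- pixels(ph) > -1 + 1e-9
  for (seed in c(1L, 22L, 333L)) {
    m <- sampleTrainingMask(c(64, 64), fg, c(0.30, 0.60), seed = seed)
    f <- sum(pixels(m)) / sum(fg)
    expect_gte(f, 0.30)
    expect_lte(f, 0.60)
    expect_true(all(pixels(m)[!fg] == 0)) # clipped to the foreground
  }
  m1 <- sampleTrainingMask(c(64, 64), fg, seed = 42)
  m2 <- sampleTrainingMask(c(64, 64), fg, seed = 42)
  expect_identical(pixels(m1), pixels(m2))
  expect_error(sampleTrainingMask(c(64, 64), fg, c(0.7, 0.2), seed = 1),
               "lo <= hi")
  expect_error(sampleTrainingMask(c(8, 8), matrix(c(1, rep(0, 63)), 8, 8),
                                  seed = 1), "too small")
})

test_that("paired datasets are reproducible triples with a split", {
  ds <- makePairedDataset(10, phantomSpec(size = 48), seed = 9)
  expect_length(ds$healthy, 10)
  expect_length(ds$pathological, 10)
  expect_length(ds$mask, 10)
  expect_true(all(vapply(ds$healthy, function(s)
    all(dim(pixels(s)) == c(48, 48)), TRUE)))
  expect_setequal(c(ds$trainIdx, ds$valIdx), 1:10)
  # ground-truth masks never swallow the whole foreground
  fr <- vapply(seq_len(10), function(i) {
    fg <- pixels(ds$healthy[[i]]) > -1 + 1e-9
    sum(pixels(ds$mask[[i]])) / sum(fg)
  }, 1)
  expect_true(all(fr < 1))
  ds2 <- makePairedDataset(10, phantomSpec(size = 48), seed = 10)
  expect_gt(max(abs(pixels(ds$healthy[[1]]) - pixels(ds2$healthy[[1]]))), 0)
  expect_error(makePairedDataset(0), "n must be")
})
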