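# Brute-force references for the attention modules: direct nested-loop
# evaluation of the cosine affinities, squared-normalized scores, patch
# transfer and residual aggregation.

bruteAttention <- function(patchMat, inside, eps = 1e-8) {
  n <- ncol(patchMat)
  aff <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    bi <- patchMat[, i]; bj <- patchMat[, j]
    aff[i, j] <- sum((bi / max(sqrt(sum(bi^2)), eps)) *
                     (bj / max(sqrt(sum(bj^2)), eps)))
  }
  s <- matrix(0, n, n)
  out <- which(!inside)
  for (j in seq_len(n)) {
    den <- 0
    for (i in out) den <- den + aff[i, j]^2
    if (den > 0) for (i in out) s[i, j] <- aff[i, j]^2 / den
    else for (i in out) s[i, j] <- 1 / length(out)
  }
  s
}

bruteTransfer <- function(patchMat, inside, s) {
  out <- patchMat
  for (j in which(inside)) {
    acc <- numeric(nrow(patchMat))
    for (i in which(!inside)) acc <- acc + s[i, j] * patchMat[, i]
    out[, j] <- acc
  }
  out
}

test_that("attention scores match Eq.-level hand examples", {
  # two context patches, one hole patch identical to the first
  pm <- cbind(c(1, 0), c(0, 1), c(1, 0))
  inside <- c(FALSE, FALSE, TRUE)
  ps <- new("PatchSet", patches = pm, patchSize = 1L, inside = inside,
            gridDim = c(1L, 3L), featDim = c(1L, 3L, 2L))
  am <- attentionScores(ps)
  expect_equal(am@affinity[1, 3], 1)
  expect_equal(am@affinity[2, 3], 0)
  expect_equal(am@scores[1:2, 3], c(1, 0))
  # squared-normalization: affinity column (0.6, 0.8) -> scores (0.36, 0.64)
  pm2 <- cbind(c(0.6, 0.8), c(1, 0), c(0, 1))
  inside2 <- c(TRUE, FALSE, FALSE)
  ps2 <- new("PatchSet", patches = pm2, patchSize = 1L, inside = inside2,
             gridDim = c(1L, 3L), featDim = c(1L, 3L, 2L))
  am2 <- attentionScores(ps2)
  expect_equal(am2@scores[2:3, 1], c(0.36, 0.64))
  # equal nonzero affinities -> uniform scores
  pm3 <- cbind(c(1, 1), c(1, 1), c(1, 1))
  ps3 <- new("PatchSet", patches = pm3, patchSize = 1L,
             inside = c(TRUE, FALSE, FALSE), gridDim = c(1L, 3L),
             featDim = c(1L, 3L, 2L))
  expect_equal(attentionScores(ps3)@scores[2:3, 1], c(0.5, 0.5))
  # nothing to attend to
  ps4 <- new("PatchSet", patches = pm3, patchSize = 1L,
             inside = rep(TRUE, 3), gridDim = c(1L, 3L),
             featDim = c(1L, 3L, 2L))
  expect_error(attentionScores(ps4), "no outside patches")
})

test_that("attention transfer follows delta and convex-combination semantics", {
  # delta scores copy the selected context patch exactly
  pm <- cbind(c(1, 2), c(3, 4), c(0, 0))
  inside <- c(FALSE, FALSE, TRUE)
  ps <- new("PatchSet", patches = pm, patchSize = 1L, inside = inside,
            gridDim = c(1L, 3L), featDim = c(1L, 3L, 2L))
  s <- matrix(0, 3, 3); s[1, 3] <- 1
  am <- new("AttentionMatrix", affinity = s, scores = s, inside = inside,
            orientation = "PIAS")
  filled <- attentionTransfer(ps, am)
  expect_equal(filled@patches[, 3], c(1, 2))
  # constant 0/1 context with weights (0.36, 0.64) fills 0.64
  pm2 <- cbind(c(0, 0), c(1, 1), c(9, 9))
  s2 <- matrix(0, 3, 3); s2[1, 3] <- 0.36; s2[2, 3] <- 0.64
  am2 <- new("AttentionMatrix", affinity = s2, scores = s2, inside = inside,
             orientation = "PIAS")
  ps2 <- new("PatchSet", patches = pm2, patchSize = 1L, inside = inside,
             gridDim = c(1L, 3L), featDim = c(1L, 3L, 2L))
  expect_equal(attentionTransfer(ps2, am2)@patches[, 3], c(0.64, 0.64))
  # identical context patches: any valid scores give the same fill
  pmv <- cbind(c(5, 5), c(5, 5), c(0, 0))
  psv <- new("PatchSet", patches = pmv, patchSize = 1L, inside = inside,
             gridDim = c(1L, 3L), featDim = c(1L, 3L, 2L))
  amv <- attentionScores(psv)
  expect_equal(attentionTransfer(psv, amv)@patches[, 3], c(5, 5))
})

test_that("vectorized attention equals the brute-force nested-loop reference", {
  set.seed(21)
  for (rep in 1:3) {
    f <- array(rnorm(64 * 64 * 2), c(64, 64, 2))
    m <- matrix(0, 64, 64)
    m[sample(64, 1) + 0:10 %% 64 + 1, sample(50, 1) + 0:8] <- 1
    ps <- extractPatches(f, 16, m)
    am <- attentionScores(ps)
    ref <- bruteAttention(ps@patches, ps@inside)
    expect_lt(max(abs(am@scores - ref)), 1e-5)
    filled <- attentionTransfer(ps, am)
    refFill <- bruteTransfer(ps@patches, ps@inside, ref)
    expect_lt(max(abs(filled@patches - refFill)), 1e-5)
  }
})

test_that("score columns are stochastic over context patches and fills are convex", {
  set.seed(33)
  for (rep in 1:20) {
    f <- array(rnorm(32 * 32), c(32, 32, 1))
    # free-form masking confined to a random band so context remains
    m <- matrix(0, 32, 32)
    m[sample(32, sample(4:20, 1)), sample(32, sample(4:20, 1))] <- 1
    ps <- extractPatches(f, 8, m)
    if (nOutside(ps) == 0 || all(!ps@inside)) next
    am <- attentionScores(ps)
    cs <- colSums(am@scores[!ps@inside, , drop = FALSE])
    expect_true(all(abs(cs - 1) < 1e-6))
    expect_true(all(am@scores >= 0))
    filled <- attentionTransfer(ps, am)
    ctx <- ps@patches[, !ps@inside, drop = FALSE]
    lo <- apply(ctx, 1, min); hi <- apply(ctx, 1, max)
    for (j in which(ps@inside)) {
      expect_true(all(filled@patches[, j] >= lo - 1e-9))
      expect_true(all(filled@patches[, j] <= hi + 1e-9))
    }
  }
})

test_that("residual images are high-pass and aggregation matches the loop oracle", {
  # constant image: up(down(const)) = const, residual identically zero
  cst <- matrix(0.4, 64, 64)
  expect_lt(max(abs(residualImage(cst, 4))), 1e-9)
  set.seed(44)
  img <- matrix(runif(64 * 64, -1, 1), 64, 64)
  r <- residualImage(img, 4)
  lo <- pseudohealthy:::.downsampleAvg(r, 4)
  # low-pass content removed, up to interpolation leakage: small relative
  # to the image's own low-pass magnitude (white noise is the worst case)
  expect_lt(mean(abs(lo)),
            0.5 * mean(abs(pseudohealthy:::.downsampleAvg(img, 4))))
  # on band-limited content the leakage is smaller still
  sm <- pseudohealthy:::.upsampleFactor(matrix(rnorm(64), 8, 8), 8)
  los <- pseudohealthy:::.downsampleAvg(residualImage(sm, 4), 4)
  expect_lt(mean(abs(los)), 0.25 * mean(abs(pseudohealthy:::.downsampleAvg(sm, 4))))
  m <- matrix(0, 64, 64); m[17:30, 20:40] <- 1
  ps <- extractPatches(img, 16, m)
  am <- attentionScores(ps)
  agg <- aggregateResiduals(r, am, m, 16)
  # brute force on the residual patches
  rp <- extractPatches(r, 16, m)
  ref <- bruteTransfer(rp@patches, rp@inside, am@scores)
  rp@patches <- ref
  expect_lt(max(abs(agg - scatterPatches(rp))), 1e-5)
  # zero residual stays zero
  expect_equal(aggregateResiduals(matrix(0, 64, 64), am, m, 16),
               matrix(0, 64, 64))
})
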