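# Hinge adversarial losses, spectral-normalized discriminator, and a
# perceptual loss over a frozen feature extractor.

#' Hinge discriminator loss
#'
#' \code{mean(max(0, 1 - real)) + mean(max(0, 1 + fake))}: real samples
#' should score above +1 and fakes below -1; samples beyond their margin
#' contribute nothing to the loss (zero subgradient), which is what
#' stabilizes the adversarial training.
#'
#' @param real_scores,fake_scores numeric vectors of discriminator scores
#' @return nonnegative numeric(1)
#' @export
hingeDLoss <- function(real_scores, fake_scores) {
  if (length(real_scores) == 0L || length(fake_scores) == 0L)
    stop("hingeDLoss: empty score set")
  mean(pmax(0, 1 - real_scores)) + mean(pmax(0, 1 + fake_scores))
}

#' Hinge generator loss
#'
#' Negative mean of the discriminator's scores on generated samples.
#'
#' @param fake_scores numeric vector of discriminator scores on fakes
#' @return numeric(1)
#' @export
hingeGLoss <- function(fake_scores) {
  if (length(fake_scores) == 0L) stop("hingeGLoss: empty score set")
  -mean(fake_scores)
}

#' Generator total loss
#'
#' Sum of the adversarial and perceptual terms.
#'
#' @param g_adv hinge generator loss
#' @param perceptual weighted perceptual loss
#' @return numeric(1)
#' @export
generatorTotalLoss <- function(g_adv, perceptual) {
  if (!is.finite(g_adv) || !is.finite(perceptual))
    stop("generatorTotalLoss: non-finite input")
  g_adv + perceptual
}

#' Build a frozen feature extractor for the perceptual loss
#'
#' The default backbone "random-fixed" is a deterministic, randomly
#' initialized three-stage conv net (conv-ReLU-avgpool) whose activations
#' after each stage serve as tap layers. Random fixed conv features are a
#' valid perceptual basis: the loss is a pseudometric that is zero iff the
#' tapped features agree. A pretrained VGG16 can be supplied through the
#' same interface by passing its weights as \code{params}.
#'
#' @param backbone "random-fixed" (default) or "VGG16" (requires params)
#' @param widths channels of the three stages, default c(8, 16, 32)
#' @param seed RNG seed for the fixed weights
#' @param params optional externally supplied weights
#' @return a \linkS4class{FeatureExtractor}
#' @export
buildFeatureExtractor <- function(backbone = "random-fixed",
                                  widths = c(8L, 16L, 32L), seed = 7L,
                                  params = NULL) {
  if (backbone == "VGG16" && is.null(params))
    stop("buildFeatureExtractor: VGG16 weights not supplied; ",
         "use backbone = 'random-fixed' or provide params")
  if (is.null(params)) {
    w <- as.integer(widths)
    params <- list()
    .withSeed(seed, {
      params[["f1.W"]] <- .heInit(3, 3, 1L, w[1L])
      params[["f1.b"]] <- .zeros(w[1L])
      params[["f2.W"]] <- .heInit(3, 3, w[1L], w[2L])
      params[["f2.b"]] <- .zeros(w[2L])
      params[["f3.W"]] <- .heInit(3, 3, w[2L], w[3L])
      params[["f3.b"]] <- .zeros(w[3L])
    })
  }
  new("FeatureExtractor", params = params,
      config = list(backbone = backbone, nTaps = 3L))
}

# Extractor forward: returns tap activations and caches. The first tap is
# the pre-activation linear response (a random linear projection preserves
# signed intensity, anchoring low-level reconstruction); deeper taps are
# post-ReLU.
.fxForward <- function(params, x, needCache = TRUE) {
  taps <- list(); cc <- list()
  h <- x
  for (i in 1:3) {
    cv <- .convForward(h, params[[paste0("f", i, ".W")]],
                       params[[paste0("f", i, ".b")]], pad = 1L,
                       needCache = needCache)
    a <- .reluF(cv$out)
    taps[[i]] <- if (i == 1L) cv$out else a
    mp <- .maxPool2Forward(a)
    cc[[i]] <- list(cv = cv$cache, z = cv$out, mp = mp$cache)
    h <- mp$out
  }
  list(taps = taps, cache = if (needCache) cc)
}

# Gradient of sum_i w_i * <taps_i, dtaps_i-direction> w.r.t. the input.
.fxBackwardToInput <- function(dtaps, cache) {
  dh <- NULL
  for (i in 3:1) {
    d <- if (i == 1L) NULL else dtaps[[i]]
    if (!is.null(dh)) {
      mb <- .maxPool2Backward(dh, cache[[i]]$mp)
      d <- if (is.null(d)) mb else d + mb
    }
    dz <- .reluB(d, cache[[i]]$z)
    if (i == 1L) dz <- dz + dtaps[[1L]] # pre-activation tap
    dh <- .convBackward(dz, cache[[i]]$cv)$dx
  }
  dh
}

#' Perceptual loss between target and output batches
#'
#' \code{lambda} times the mean over tap layers of the mean absolute
#' difference between the frozen extractor's feature maps of the two
#' inputs. Grayscale inputs are used as-is (the extractor is built for one
#' channel). Zero iff the tapped features agree; symmetric in its
#' arguments; linear in \code{lambda}.
#'
#' @param extractor a \linkS4class{FeatureExtractor}
#' @param target,output \linkS4class{GraySlice}s, matrices, or (H,W,1,N)
#'   arrays
#' @param lambda texture-loss weight, default 64
#' @return nonnegative numeric(1)
#' @export
perceptualLoss <- function(extractor, target, output, lambda = 64) {
  stopifnot(is(extractor, "FeatureExtractor"))
  toBatch <- function(x) {
    if (is(x, "GraySlice")) x <- x@pixels
    if (is.list(x)) return(.stackBatch(lapply(x, function(z)
      if (is(z, "GraySlice")) z@pixels else z)))
    if (is.matrix(x)) x <- array(x, c(dim(x), 1L, 1L))
    x
  }
  a <- toBatch(target); b <- toBatch(output)
  if (!all(dim(a) == dim(b))) stop("perceptualLoss: shape mismatch")
  fa <- .fxForward(extractor@params, a, needCache = FALSE)$taps
  fb <- .fxForward(extractor@params, b, needCache = FALSE)$taps
  lambda * mean(vapply(1:3, function(i) mean(abs(fa[[i]] - fb[[i]])), 1))
}

# Perceptual loss + gradient w.r.t. output batch (for generator training).
.perceptualLossGrad <- function(extractor, target, output, lambda = 64) {
  fa <- .fxForward(extractor@params, target, needCache = FALSE)$taps
  fb <- .fxForward(extractor@params, output, needCache = TRUE)
  diffs <- lapply(1:3, function(i) fb$taps[[i]] - fa[[i]])
  loss <- lambda * mean(vapply(diffs, function(d) mean(abs(d)), 1))
  dtaps <- lapply(diffs, function(d) {
    g <- sign(d) / length(d) # d/dx of mean|x|
    g * (lambda / 3)
  })
  grad <- .fxBackwardToInput(dtaps, fb$cache)
  list(loss = loss, grad = grad)
}

#' Build an untrained spectral-normalized discriminator
#'
#' Five strided convolutions with leaky-ReLU activations and spectral
#' normalization, followed by a 1-channel score map that is mean-reduced
#' to a scalar per image: the stable default for hinge-GAN inpainting.
#'
#' @param baseWidth first-layer channels (default 32)
#' @param seed RNG seed
#' @return a \linkS4class{DiscriminatorModel}
#' @export
buildDiscriminator <- function(baseWidth = 32L, seed = 1L) {
  c1 <- as.integer(baseWidth)
  w <- c(c1, 2L * c1, 4L * c1, 4L * c1, 4L * c1)
  params <- list()
  .withSeed(seed, {
    cin <- 1L
    for (i in 1:5) {
      params[[paste0("c", i, ".W")]] <- .heInit(3, 3, cin, w[i])
      params[[paste0("c", i, ".b")]] <- .zeros(w[i])
      cin <- w[i]
    }
    params[["s.W"]] <- .heInit(3, 3, w[5L], 1L, gain = 1)
    params[["s.b"]] <- .zeros(1L)
  })
  new("DiscriminatorModel", params = params,
      config = list(baseWidth = c1,
                    u = replicate(6, NULL, simplify = FALSE)))
}

# Discriminator forward: returns per-image scalar scores. Spectral norms
# are estimated with one persistent power-iteration step per weight; the
# updated iteration vectors are returned so the caller can carry them.
.discForward <- function(params, uvecs, x, needCache = TRUE) {
  cc <- list(); sig <- numeric(6)
  h <- x
  for (i in 1:5) {
    W <- params[[paste0("c", i, ".W")]]
    sn <- .spectralNorm(W, uvecs[[i]])
    uvecs[[i]] <- sn$u; sig[i] <- sn$sigma
    cv <- .convForward(h, W / sn$sigma, params[[paste0("c", i, ".b")]],
                       stride = 2L, pad = 1L, needCache = needCache)
    a <- .lreluF(cv$out)
    cc[[i]] <- list(cv = cv$cache, z = cv$out)
    h <- a
  }
  Ws <- params[["s.W"]]
  sn <- .spectralNorm(Ws, uvecs[[6L]])
  uvecs[[6L]] <- sn$u; sig[6L] <- sn$sigma
  sv <- .convForward(h, Ws / sn$sigma, params[["s.b"]], pad = 1L,
                     needCache = needCache)
  scoreMap <- sv$out # (h', w', 1, N)
  scores <- apply(scoreMap, 4L, mean)
  list(scores = scores, u = uvecs,
       cache = if (needCache) list(cc = cc, sv = sv$cache,
                                   mapDim = dim(scoreMap), sig = sig))
}

# Backward given d(scores) (one value per image). Returns grads and dx.
.discBackward <- function(dscores, cache, needDx = FALSE) {
  md <- cache$mapDim
  dmap <- array(rep(dscores, each = prod(md[1:3])) / prod(md[1:3]), md)
  g <- list()
  bs <- .convBackward(dmap, cache$sv)
  # grads w.r.t. raw weights: scale by 1/sigma (sigma held constant)
  g[["s.W"]] <- bs$dW / cache$sig[6L]; g[["s.b"]] <- bs$db
  dh <- bs$dx
  for (i in 5:1) {
    dz <- .lreluB(dh, cache$cc[[i]]$z)
    bi <- .convBackward(dz, cache$cc[[i]]$cv, needDx = i > 1L || needDx)
    g[[paste0("c", i, ".W")]] <- bi$dW / cache$sig[i]
    g[[paste0("c", i, ".b")]] <- bi$db
    dh <- bi$dx
  }
  list(grads = g, dx = dh)
}
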