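# Stage 3: refinement generator. Fully symmetric dual-path encoder (shared
# weights on the slice and its horizontal flip), contextual attention at
# the deepest feature level, channel fusion, decoder, and full-resolution
# contextual residual aggregation driven by the forward-path (PIAS) scores.
#
# Attention scores are treated as constants during backpropagation;
# gradients flow through the patch values and the direct encoder streams.

#' Build an untrained refinement generator
#'
#' The encoder downsamples twice (H -> H/4); attention operates on the
#' deepest feature map with a feature-level patch of
#' \code{patchSize / 4}, so the patch grid matches the image-level
#' patchSize x patchSize tiling used for residual aggregation. At the
#' default 256 x 256 attention resolution with patch 16 this gives 256
#' patches and a 256 x 256 affinity matrix.
#'
#' @param baseWidth encoder width at full resolution (default 32)
#' @param patchSize image-level attention patch side (default 16)
#' @param useCra enable contextual residual attention (default TRUE)
#' @param useFlip enable the flipped path (requires useCra; default TRUE)
#' @param seed RNG seed for initialization
#' @return a \linkS4class{GeneratorModel}
#' @export
buildGenerator <- function(baseWidth = 32L, patchSize = 16L, useCra = TRUE,
                           useFlip = TRUE, seed = 1L) {
  if (useFlip && !useCra)
    stop("buildGenerator: useFlip requires useCra")
  c1 <- as.integer(baseWidth)
  nStream <- if (!useCra) 1L else if (!useFlip) 2L else 4L
  params <- list()
  .withSeed(seed, {
    params[["e1.W"]] <- .heInit(5, 5, 2L, c1); params[["e1.b"]] <- .zeros(c1)
    # strided convs use even 4x4 kernels: their sampling grid is mirror-
    # symmetric, which the dual-path flip structure relies on
    params[["e2.W"]] <- .heInit(4, 4, c1, 2L * c1)
    params[["e2.b"]] <- .zeros(2L * c1)
    params[["e3.W"]] <- .heInit(4, 4, 2L * c1, 4L * c1)
    params[["e3.b"]] <- .zeros(4L * c1)
    params[["d0.W"]] <- .heInit(3, 3, nStream * 4L * c1, 4L * c1)
    if (useFlip) {
      # the flip streams start silent: the fusion recruits the mirrored
      # features only where gradients support them, so enabling the flip
      # path never starts worse than the forward-only configuration
      params[["d0.W"]][, , c(4L * c1 + 1:(4L * c1),
                             12L * c1 + 1:(4L * c1)), ] <- 0
    }
    params[["d0.b"]] <- .zeros(4L * c1)
    params[["d1.W"]] <- .heInit(3, 3, 4L * c1, 2L * c1)
    params[["d1.b"]] <- .zeros(2L * c1)
    params[["d2.W"]] <- .heInit(3, 3, 2L * c1, c1)
    params[["d2.b"]] <- .zeros(c1)
    # with CRA the decoder predicts a correction to the blurry fill: its
    # output conv starts at zero (the standard residual-branch init), so
    # the untrained generator is the identity-plus-residual merge. The
    # plain encoder-decoder keeps a unit-gain output.
    params[["out.W"]] <- if (useCra) array(0, c(3, 3, c1, 1L))
                         else .heInit(3, 3, c1, 1L, gain = 1)
    params[["out.b"]] <- .zeros(1L)
  })
  new("GeneratorModel", params = params,
      config = list(baseWidth = c1, patchSize = as.integer(patchSize),
                    useCra = useCra, useFlip = useFlip,
                    residualFactor = 2L, trained = FALSE))
}

# Block-wise "any" reduction of a full-resolution mask to feature scale.
.maskToFeature <- function(m, k) {
  h <- nrow(m); w <- ncol(m)
  a <- array(m, c(k, h %/% k, w))
  a <- apply(a, c(2, 3), max)
  a <- array(t(a), c(k, w %/% k, h %/% k))
  t(apply(a, c(2, 3), max))
}

# Shared-weight encoder on (H, W, 2, N).
.genEncForward <- function(params, x, needCache = TRUE) {
  c1 <- .convForward(x, params[["e1.W"]], params[["e1.b"]], pad = 2L,
                     needCache = needCache)
  a1 <- .eluF(c1$out)
  c2 <- .convForward(a1, params[["e2.W"]], params[["e2.b"]], stride = 2L,
                     pad = 1L, needCache = needCache)
  a2 <- .eluF(c2$out)
  c3 <- .convForward(a2, params[["e3.W"]], params[["e3.b"]], stride = 2L,
                     pad = 1L, needCache = needCache)
  a3 <- .eluF(c3$out)
  list(out = a3, cache = if (needCache) list(c1 = c1$cache, a1 = a1,
                                             c2 = c2$cache, a2 = a2,
                                             c3 = c3$cache, a3 = a3))
}

.genEncBackward <- function(dout, cache, needDx = FALSE) {
  g <- list()
  dz3 <- .eluB(dout, cache$a3)
  b3 <- .convBackward(dz3, cache$c3)
  g[["e3.W"]] <- b3$dW; g[["e3.b"]] <- b3$db
  dz2 <- .eluB(b3$dx, cache$a2)
  b2 <- .convBackward(dz2, cache$c2)
  g[["e2.W"]] <- b2$dW; g[["e2.b"]] <- b2$db
  dz1 <- .eluB(b2$dx, cache$a1)
  b1 <- .convBackward(dz1, cache$c1, needDx = needDx)
  g[["e1.W"]] <- b1$dW; g[["e1.b"]] <- b1$db
  list(grads = g, dx = b1$dx)
}

# Attention fill of a feature tensor, per sample. Returns filled tensor,
# the per-sample score objects, and what the backward pass needs.
.attFill <- function(feat, masksF, pf) {
  d <- dim(feat); N <- d[4L]
  out <- feat
  scores <- vector("list", N)
  for (n in seq_len(N)) {
    pset <- extractPatches(feat[, , , n, drop = TRUE], pf, masksF[[n]])
    # nothing to fill, or no context to draw from: leave the map as-is
    if (all(!pset@inside) || all(pset@inside)) { scores[n] <- list(NULL); next }
    am <- attentionScores(pset)
    filled <- attentionTransfer(pset, am)
    out[, , , n] <- scatterPatches(filled, drop = FALSE)
    scores[[n]] <- am
  }
  list(out = out, scores = scores, pf = pf)
}

# Backward through the attention fill value path (scores constant).
.attFillBackward <- function(dout, att, masksF) {
  d <- dim(dout); N <- d[4L]
  dx <- dout
  for (n in seq_len(N)) {
    am <- att$scores[[n]]
    if (is.null(am)) next
    dp <- extractPatches(dout[, , , n, drop = TRUE], att$pf, masksF[[n]])
    dF <- dp@patches
    S <- am@scores
    inside <- am@inside
    dP <- dF
    dP[, inside] <- 0 # replaced patches pass nothing through directly
    dP <- dP + dF[, inside, drop = FALSE] %*% t(S[, inside, drop = FALSE])
    dp@patches <- dP
    dx[, , , n] <- scatterPatches(dp, drop = FALSE)
  }
  dx
}

# Full generator forward on paired lists of matrices (vague, mask).
# Returns the refined batch plus caches for backprop.
.genForward <- function(params, cfg, vagues, masks, needCache = TRUE) {
  N <- length(vagues)
  H <- nrow(vagues[[1L]]); W <- ncol(vagues[[1L]])
  ps <- cfg$patchSize
  if (H %% ps != 0L || W %% ps != 0L)
    stop("generator: dims must be divisible by patchSize")
  pf <- ps %/% 4L
  x <- array(0, c(H, W, 2L, N))
  for (n in seq_len(N)) {
    x[, , 1L, n] <- vagues[[n]]
    x[, , 2L, n] <- masks[[n]]
  }
  enc <- .genEncForward(params, x, needCache)
  LF <- enc$out
  masksF <- lapply(masks, .maskToFeature, k = 4L)
  streams <- list(LF)
  encF <- NULL; attP <- NULL; attF <- NULL
  if (cfg$useCra) {
    attP <- .attFill(LF, masksF, pf)
    if (cfg$useFlip) {
      xf <- x[, rev(seq_len(W)), , , drop = FALSE]
      encF <- .genEncForward(params, xf, needCache)
      masksFf <- lapply(masksF, horizontalFlip)
      attF <- .attFill(encF$out, masksFf, pf)
      streams <- list(LF,
                      encF$out[, rev(seq_len(W %/% 4L)), , , drop = FALSE],
                      attP$out,
                      attF$out[, rev(seq_len(W %/% 4L)), , , drop = FALSE])
    } else {
      streams <- list(LF, attP$out)
    }
  }
  fuse <- do.call(.catChannels, streams)
  d0 <- .convForward(fuse, params[["d0.W"]], params[["d0.b"]], pad = 1L,
                     needCache = needCache)
  a0 <- .eluF(d0$out)
  u1 <- .upsample2Forward(a0)
  d1 <- .convForward(u1, params[["d1.W"]], params[["d1.b"]], pad = 1L,
                     needCache = needCache)
  a1 <- .eluF(d1$out)
  u2 <- .upsample2Forward(a1)
  d2 <- .convForward(u2, params[["d2.W"]], params[["d2.b"]], pad = 1L,
                     needCache = needCache)
  a2 <- .eluF(d2$out)
  oc <- .convForward(a2, params[["out.W"]], params[["out.b"]], pad = 1L,
                     needCache = needCache)
  g <- tanh(oc$out)
  pre <- g
  if (cfg$useCra) {
    # Eq.-10-style merge: the stage-2 fill is the blurry image; the decoder
    # contributes a learned correction and the aggregated residual
    # transplants matching high-frequency texture into the hole.
    for (n in seq_len(N)) {
      pre[, , 1L, n] <- pre[, , 1L, n] + vagues[[n]]
      if (is.null(attP$scores[[n]])) next
      r <- residualImage(vagues[[n]], cfg$residualFactor %||% 2L)
      ragg <- aggregateResiduals(r, attP$scores[[n]], masks[[n]], ps)
      pre[, , 1L, n] <- pre[, , 1L, n] + masks[[n]] * ragg
    }
  }
  outc <- .clampF(pre)
  refined <- outc
  for (n in seq_len(N))
    refined[, , 1L, n] <- masks[[n]] * outc[, , 1L, n] +
      (1 - masks[[n]]) * vagues[[n]]
  cache <- if (needCache)
    list(enc = enc$cache, encF = if (!is.null(encF)) encF$cache,
         attP = attP, attF = attF, masksF = masksF, masks = masks,
         d0 = d0$cache, a0 = a0, d1 = d1$cache, a1 = a1, d2 = d2$cache,
         a2 = a2, oc = oc$cache, g = g, pre = pre,
         streamC = vapply(streams, function(s) dim(s)[3L], 1L),
         W4 = W %/% 4L, cfg = cfg)
  list(out = refined, cache = cache)
}

# Backward from d(refined); returns parameter gradients.
.genBackward <- function(dout, cache) {
  cfg <- cache$cfg
  N <- dim(dout)[4L]
  dpre <- dout
  for (n in seq_len(N)) # composite: only the masked region reaches G
    dpre[, , 1L, n] <- dout[, , 1L, n] * cache$masks[[n]]
  dpre <- .clampB(dpre, cache$pre)
  dg <- dpre # the residual-aggregation addend is constant w.r.t. params
  dz <- .tanhB(dg, cache$g)
  g <- list()
  bo <- .convBackward(dz, cache$oc)
  g[["out.W"]] <- bo$dW; g[["out.b"]] <- bo$db
  da2 <- .eluB(bo$dx, cache$a2)
  b2 <- .convBackward(da2, cache$d2)
  g[["d2.W"]] <- b2$dW; g[["d2.b"]] <- b2$db
  da1 <- .eluB(.upsample2Backward(b2$dx), cache$a1)
  b1 <- .convBackward(da1, cache$d1)
  g[["d1.W"]] <- b1$dW; g[["d1.b"]] <- b1$db
  da0 <- .eluB(.upsample2Backward(b1$dx), cache$a0)
  b0 <- .convBackward(da0, cache$d0)
  g[["d0.W"]] <- b0$dW; g[["d0.b"]] <- b0$db
  # split fusion gradient into streams
  sc <- cache$streamC
  dfuse <- b0$dx
  at <- 0L
  dstream <- vector("list", length(sc))
  for (i in seq_along(sc)) {
    dstream[[i]] <- dfuse[, , at + seq_len(sc[i]), , drop = FALSE]
    at <- at + sc[i]
  }
  W4 <- cache$W4
  dLF <- dstream[[1L]]
  dLFf <- NULL
  if (cfg$useCra) {
    if (cfg$useFlip) {
      dLFf <- dstream[[2L]][, rev(seq_len(W4)), , , drop = FALSE]
      dLF <- dLF + .attFillBackward(dstream[[3L]], cache$attP, cache$masksF)
      dAttF <- dstream[[4L]][, rev(seq_len(W4)), , , drop = FALSE]
      masksFf <- lapply(cache$masksF, horizontalFlip)
      dLFf <- dLFf + .attFillBackward(dAttF, cache$attF, masksFf)
    } else {
      dLF <- dLF + .attFillBackward(dstream[[2L]], cache$attP, cache$masksF)
    }
  }
  be <- .genEncBackward(dLF, cache$enc)
  g <- .gradAdd(g, be$grads)
  if (!is.null(dLFf)) {
    bef <- .genEncBackward(dLFf, cache$encF)
    g <- .gradAdd(g, bef$grads) # shared weights: contributions sum
  }
  g
}

#' Refine a coarse-filled slice
#'
#' Runs the flip-symmetric dual-path pipeline: (a) the coarse fill and its
#' horizontal flip pass through the shared-weight encoder; (b) the
#' Attention Calculation Module computes the forward (PIAS) and flipped
#' (FIAS) score matrices; (c) the Attention Transfer Module fills the
#' masked feature patches on each path; (d) flipped-path tensors are
#' re-flipped and all streams are fused channel-wise and decoded; (e) the
#' full-resolution high-frequency residual of the coarse fill is
#' aggregated with the PIAS scores and added inside the mask; (f) the
#' result is composited so pixels outside the mask equal the input
#' bit-exactly.
#'
#' @param model a \linkS4class{GeneratorModel}
#' @param vague a \linkS4class{GraySlice}: the coarse fill from
#'   \code{\link{vagueFill}}
#' @param mask a \linkS4class{LesionMask} of the same shape
#' @return a \linkS4class{GraySlice} in [-1, 1]
#' @export
refineSlice <- function(model, vague, mask) {
  stopifnot(is(model, "GeneratorModel"), is(vague, "GraySlice"),
            is(mask, "LesionMask"))
  if (!all(dim(vague@pixels) == dim(mask@pixels)))
    stop("refineSlice: shape mismatch")
  fw <- .genForward(model@params, model@config, list(vague@pixels),
                    list(mask@pixels), needCache = FALSE)
  GraySlice(fw$out[, , 1L, 1L], vague@spacing)
}

# Left-right symmetrize every conv kernel of a model. With symmetric
# kernels convolution commutes with horizontal flips, which makes the
# whole generator exactly flip-equivariant -- used to test the dual-path
# plumbing (shared weights, re-flips, attention index relabelling).
.symmetrizeKernels <- function(model) {
  p <- model@params
  for (nm in names(p)) {
    d <- dim(p[[nm]])
    if (length(d) == 4L && d[2L] > 1L)
      p[[nm]] <- (p[[nm]] + p[[nm]][, rev(seq_len(d[2L])), , ,
                                    drop = FALSE]) / 2
  }
  model@params <- p
  model
}
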