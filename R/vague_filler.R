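# Stage 2: coarse inpainting. A straight-line residual chain of gated
# convolutions (no skip connections) working mostly at H/4 resolution,
# trained with L1 loss only against the original healthy slice.

# Gated convolution: out = ELU(conv_f(x)) * sigmoid(conv_g(x)); two
# parallel convolutions per layer. The gate lets the network modulate each
# spatial position, which is what makes free-form masks tractable.
.gconvForward <- function(x, p, pre, stride = 1L, pad = 0L, dilation = 1L,
                          needCache = TRUE) {
  cf <- .convForward(x, p[[paste0(pre, ".Wf")]], p[[paste0(pre, ".bf")]],
                     stride, pad, dilation, needCache)
  cg <- .convForward(x, p[[paste0(pre, ".Wg")]], p[[paste0(pre, ".bg")]],
                     stride, pad, dilation, needCache)
  a <- .eluF(cf$out)
  g <- .sigmoidF(cg$out)
  list(out = a * g,
       cache = if (needCache) list(cf = cf$cache, cg = cg$cache,
                                   a = a, g = g, pre = pre))
}

.gconvBackward <- function(dout, cache, needDx = TRUE) {
  da <- dout * cache$g
  dg <- dout * cache$a
  dzf <- .eluB(da, cache$a)
  dzg <- .sigmoidB(dg, cache$g)
  bf <- .convBackward(dzf, cache$cf, needDx)
  bg <- .convBackward(dzg, cache$cg, needDx)
  g <- list()
  g[[paste0(cache$pre, ".Wf")]] <- bf$dW
  g[[paste0(cache$pre, ".bf")]] <- bf$db
  g[[paste0(cache$pre, ".Wg")]] <- bg$dW
  g[[paste0(cache$pre, ".bg")]] <- bg$db
  list(dx = if (needDx) bf$dx + bg$dx, grads = g)
}

.gconvInit <- function(params, pre, kh, kw, cin, cout) {
  params[[paste0(pre, ".Wf")]] <- .heInit(kh, kw, cin, cout)
  params[[paste0(pre, ".bf")]] <- .zeros(cout)
  params[[paste0(pre, ".Wg")]] <- .heInit(kh, kw, cin, cout, gain = 1)
  params[[paste0(pre, ".bg")]] <- .zeros(cout)
  params
}

#' Build an untrained coarse-filler network
#'
#' Gated convolutions are the sole learnable mechanism. The input
#' (masked image + mask, two channels) is taken to H/2 and then H/4 by two
#' strided gated convolutions, processed by a straight-line chain of
#' residual dilated gated-conv blocks at H/4 (no skip connections), and
#' brought back to full resolution by interpolation + gated convolution,
#' with a tanh output. Default widths 32/64/128 and six blocks with
#' dilations 1,2,4,8,4,2; desk-scale training uses narrower widths.
#'
#' @param widths integer(3): channels at H/2, H/4, and in the blocks
#' @param dilations dilation of each residual block
#' @param seed RNG seed for initialization
#' @return a \linkS4class{VagueFillerModel}
#' @export
buildVagueFiller <- function(widths = c(32L, 64L, 128L),
                             dilations = c(1L, 2L, 4L, 8L, 4L, 2L),
                             seed = 1L) {
  w <- as.integer(widths)
  params <- list()
  .withSeed(seed, {
    params <- .gconvInit(params, "g1", 5, 5, 2L, w[1L])
    params <- .gconvInit(params, "g2", 3, 3, w[1L], w[2L])
    params <- .gconvInit(params, "g3", 3, 3, w[2L], w[3L])
    for (k in seq_along(dilations))
      params <- .gconvInit(params, paste0("blk", k), 3, 3, w[3L], w[3L])
    params <- .gconvInit(params, "u1", 3, 3, w[3L], w[2L])
    params <- .gconvInit(params, "u2", 3, 3, w[2L], w[1L])
    params[["out.W"]] <- .heInit(3, 3, w[1L], 1L, gain = 1)
    params[["out.b"]] <- .zeros(1L)
  })
  new("VagueFillerModel", params = params,
      config = list(widths = w, dilations = as.integer(dilations),
                    trained = FALSE))
}

# Forward pass; x is (H, W, 2, N) = [image * (1-mask), mask].
.fillerForward <- function(params, cfg, x, needCache = TRUE) {
  cc <- list()
  g1 <- .gconvForward(x, params, "g1", stride = 2L, pad = 2L,
                      needCache = needCache)
  g2 <- .gconvForward(g1$out, params, "g2", stride = 2L, pad = 1L,
                      needCache = needCache)
  g3 <- .gconvForward(g2$out, params, "g3", pad = 1L, needCache = needCache)
  h <- g3$out
  blk <- list()
  for (k in seq_along(cfg$dilations)) {
    d <- cfg$dilations[k]
    b <- .gconvForward(h, params, paste0("blk", k), pad = d, dilation = d,
                       needCache = needCache)
    h <- h + b$out # residual connection
    blk[[k]] <- b$cache
  }
  u1in <- .upsample2Forward(h)
  u1 <- .gconvForward(u1in, params, "u1", pad = 1L, needCache = needCache)
  u2in <- .upsample2Forward(u1$out)
  u2 <- .gconvForward(u2in, params, "u2", pad = 1L, needCache = needCache)
  oc <- .convForward(u2$out, params[["out.W"]], params[["out.b"]], pad = 1L,
                     needCache = needCache)
  out <- tanh(oc$out)
  cache <- if (needCache) list(g1 = g1$cache, g2 = g2$cache, g3 = g3$cache,
                               blk = blk, u1 = u1$cache, u2 = u2$cache,
                               oc = oc$cache, tout = out,
                               nblk = length(cfg$dilations))
  list(out = out, cache = cache)
}

.fillerBackward <- function(dout, cache) {
  g <- list()
  dz <- .tanhB(dout, cache$tout)
  bo <- .convBackward(dz, cache$oc)
  g[["out.W"]] <- bo$dW; g[["out.b"]] <- bo$db
  b2 <- .gconvBackward(bo$dx, cache$u2)
  g <- .gradAdd(g, b2$grads)
  dh <- .upsample2Backward(b2$dx)
  b1 <- .gconvBackward(dh, cache$u1)
  g <- .gradAdd(g, b1$grads)
  dh <- .upsample2Backward(b1$dx)
  for (k in rev(seq_len(cache$nblk))) {
    bb <- .gconvBackward(dh, cache$blk[[k]])
    g <- .gradAdd(g, bb$grads)
    dh <- dh + bb$dx # residual: gradient flows through both branches
  }
  b3 <- .gconvBackward(dh, cache$g3)
  g <- .gradAdd(g, b3$grads)
  bg2 <- .gconvBackward(b3$dx, cache$g2)
  g <- .gradAdd(g, bg2$grads)
  bg1 <- .gconvBackward(bg2$dx, cache$g1, needDx = FALSE)
  g <- .gradAdd(g, bg1$grads)
  g
}

# Build the 2-channel filler input from slices and masks.
.fillerInput <- function(imgs, masks) {
  n <- length(imgs)
  H <- nrow(imgs[[1L]]@pixels); W <- ncol(imgs[[1L]]@pixels)
  x <- array(0, c(H, W, 2L, n))
  for (i in seq_len(n)) {
    m <- masks[[i]]@pixels
    x[, , 1L, i] <- imgs[[i]]@pixels * (1 - m)
    x[, , 2L, i] <- m
  }
  x
}

#' Coarse-fill the masked region of a slice
#'
#' The masked image (original pre-multiplied by \code{1 - mask}) and the
#' mask are concatenated as two input channels, so the network never reads
#' the masked pixels of the original. The output is a full-resolution slice
#' in [-1, 1] (tanh): a blurry but anatomically plausible healthy fill.
#'
#' @param model a \linkS4class{VagueFillerModel}
#' @param img a \linkS4class{GraySlice} (dims divisible by 4)
#' @param mask a \linkS4class{LesionMask} of the same shape
#' @return a \linkS4class{GraySlice}
#' @export
vagueFill <- function(model, img, mask) {
  stopifnot(is(model, "VagueFillerModel"), is(img, "GraySlice"),
            is(mask, "LesionMask"))
  if (!all(dim(img@pixels) == dim(mask@pixels)))
    stop("vagueFill: image and mask shapes differ")
  if (nrow(img@pixels) %% 4L != 0L || ncol(img@pixels) %% 4L != 0L)
    stop("vagueFill: dims must be divisible by 4")
  x <- .fillerInput(list(img), list(mask))
  out <- .fillerForward(model@params, model@config, x, needCache = FALSE)$out
  GraySlice(out[, , 1L, 1L], img@spacing)
}

#' Mean absolute (L1) loss
#'
#' Mean over all pixels and batch items of \eqn{|pred - target|}. Zero iff
#' the inputs are identical; symmetric in its arguments.
#'
#' @param pred,target \linkS4class{GraySlice}s, matrices, arrays, or lists
#'   thereof (paired)
#' @return nonnegative numeric(1)
#' @export
l1Loss <- function(pred, target) {
  toArr <- function(x) {
    if (is.list(x)) unlist(lapply(x, toArr), use.names = FALSE)
    else if (is(x, "GraySlice") || is(x, "LesionMask")) as.vector(x@pixels)
    else as.vector(x)
  }
  a <- toArr(pred); b <- toArr(target)
  if (length(a) != length(b)) stop("l1Loss: shape mismatch")
  mean(abs(a - b))
}

#' Train the coarse filler on healthy slices
#'
#' Per step: draw a batch of healthy slices, sample a fresh free-form mask
#' covering 30-60\% of each slice's foreground, coarse-fill, and minimize
#' the L1 loss against the original slice with Adam. The learning rate
#' starts at \code{lr} and halves every \code{lrHalveEvery} epochs.
#'
#' @param model a \linkS4class{VagueFillerModel}
#' @param healthy list of healthy \linkS4class{GraySlice}s
#' @param config list: \code{steps} (if given, overrides epochs),
#'   \code{epochs} (10), \code{batch} (4), \code{lr} (1e-3),
#'   \code{lrHalveEvery} (5), \code{ratioRange} (c(0.30, 0.60)),
#'   \code{seed} (1)
#' @return list with \code{model} (trained) and \code{history} (per-step
#'   L1 loss)
#' @export
trainVagueFiller <- function(model, healthy, config = list()) {
  if (length(healthy) < 1L) stop("trainVagueFiller: no training slices")
  cfg <- modifyList(list(steps = NULL, epochs = 10L, batch = 4L, lr = 1e-3,
                         lrHalveEvery = 5L, ratioRange = c(0.30, 0.60),
                         seed = 1L), config)
  params <- model@params
  mcfg <- model@config
  n <- length(healthy)
  batch <- min(cfg$batch, n)
  stepsPerEpoch <- max(1L, ceiling(n / batch))
  nsteps <- if (!is.null(cfg$steps)) cfg$steps else cfg$epochs * stepsPerEpoch
  st <- .adamInit(params)
  history <- numeric(nsteps)
  .withSeed(cfg$seed, {
    for (step in seq_len(nsteps)) {
      epoch <- (step - 1L) %/% stepsPerEpoch
      lr <- lrSchedule(cfg$lr, epoch, cfg$lrHalveEvery)
      bi <- sample.int(n, batch, replace = batch > n)
      imgs <- healthy[bi]
      mseeds <- sample.int(.Machine$integer.max - 1L, batch)
      msk <- lapply(seq_len(batch), function(j) {
        fg <- imgs[[j]]@pixels > -1 + 1e-9
        sampleTrainingMask(dim(fg), fg, cfg$ratioRange, seed = mseeds[j],
                           spacing = imgs[[j]]@spacing)
      })
      x <- .fillerInput(imgs, msk)
      tgt <- .stackBatch(lapply(imgs, pixels))
      fw <- .fillerForward(params, mcfg, x)
      diff <- fw$out - tgt
      history[step] <- mean(abs(diff))
      dout <- sign(diff) / length(diff)
      gr <- .fillerBackward(dout, fw$cache)
      if (lr > 0) {
        upd <- .adamStep(params, gr, st, lr)
        params <- upd$params; st <- upd$state
      }
    }
  })
  out <- new("VagueFillerModel", params = params,
             config = c(mcfg[setdiff(names(mcfg), "trained")],
                        list(trained = TRUE)))
  list(model = out, history = history)
}
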