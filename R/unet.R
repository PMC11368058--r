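# U-Net: encoder-decoder with skip connections, 3x3 convs + ReLU, 2x2 max
# pooling, nearest-upsampling decoder, 1x1 output conv producing logits.
# Fully convolutional: works on any input whose dims divide by 2^depth.

.unetWidths <- function(base, depth) base * 2L^(0:(depth)) # depth+1 entries

#' Build an untrained U-Net parameter set
#'
#' @param baseWidth channels at the first level (default 32, the canonical
#'   configuration; desk-scale training uses smaller widths)
#' @param depth number of pooling stages (default 4)
#' @param inChannels input channels (default 1)
#' @param seed RNG seed for the Kaiming initialization
#' @return a \linkS4class{SegmentorModel} with untrained parameters
#' @export
buildUnet <- function(baseWidth = 32L, depth = 4L, inChannels = 1L,
                      seed = 1L) {
  w <- .unetWidths(as.integer(baseWidth), as.integer(depth))
  params <- list()
  .withSeed(seed, {
    cin <- inChannels
    for (l in seq_len(depth)) {
      params[[paste0("e", l, ".W1")]] <- .heInit(3, 3, cin, w[l])
      params[[paste0("e", l, ".b1")]] <- .zeros(w[l])
      params[[paste0("e", l, ".W2")]] <- .heInit(3, 3, w[l], w[l])
      params[[paste0("e", l, ".b2")]] <- .zeros(w[l])
      cin <- w[l]
    }
    params[["bot.W1"]] <- .heInit(3, 3, w[depth], w[depth + 1L])
    params[["bot.b1"]] <- .zeros(w[depth + 1L])
    params[["bot.W2"]] <- .heInit(3, 3, w[depth + 1L], w[depth + 1L])
    params[["bot.b2"]] <- .zeros(w[depth + 1L])
    for (l in seq_len(depth)) {
      above <- if (l == depth) w[depth + 1L] else w[l + 1L]
      params[[paste0("d", l, ".Wu")]] <- .heInit(3, 3, above, w[l])
      params[[paste0("d", l, ".bu")]] <- .zeros(w[l])
      params[[paste0("d", l, ".W1")]] <- .heInit(3, 3, 2L * w[l], w[l])
      params[[paste0("d", l, ".b1")]] <- .zeros(w[l])
      params[[paste0("d", l, ".W2")]] <- .heInit(3, 3, w[l], w[l])
      params[[paste0("d", l, ".b2")]] <- .zeros(w[l])
    }
    params[["out.W"]] <- .heInit(1, 1, w[1L], 1L, gain = 1)
    params[["out.b"]] <- .zeros(1L)
  })
  new("SegmentorModel", params = params,
      config = list(baseWidth = as.integer(baseWidth),
                    depth = as.integer(depth),
                    inChannels = as.integer(inChannels), trained = FALSE),
      threshold = 0.5)
}

# Forward pass; x is (H, W, inChannels, N). Returns logits and cache.
.unetForward <- function(params, cfg, x, needCache = TRUE) {
  depth <- cfg$depth
  cc <- list(); skips <- list()
  h <- x
  for (l in seq_len(depth)) {
    c1 <- .convForward(h, params[[paste0("e", l, ".W1")]],
                       params[[paste0("e", l, ".b1")]], pad = 1L,
                       needCache = needCache)
    a1 <- .reluF(c1$out)
    c2 <- .convForward(a1, params[[paste0("e", l, ".W2")]],
                       params[[paste0("e", l, ".b2")]], pad = 1L,
                       needCache = needCache)
    a2 <- .reluF(c2$out)
    mp <- .maxPool2Forward(a2)
    skips[[l]] <- a2
    if (needCache)
      cc[[paste0("e", l)]] <- list(c1 = c1$cache, z1 = c1$out, c2 = c2$cache,
                                   z2 = c2$out, mp = mp$cache)
    h <- mp$out
  }
  b1 <- .convForward(h, params[["bot.W1"]], params[["bot.b1"]], pad = 1L,
                     needCache = needCache)
  ab1 <- .reluF(b1$out)
  b2 <- .convForward(ab1, params[["bot.W2"]], params[["bot.b2"]], pad = 1L,
                     needCache = needCache)
  h <- .reluF(b2$out)
  if (needCache) cc[["bot"]] <- list(c1 = b1$cache, z1 = b1$out,
                                     c2 = b2$cache, z2 = b2$out)
  for (l in rev(seq_len(depth))) {
    u <- .upsample2Forward(h)
    cu <- .convForward(u, params[[paste0("d", l, ".Wu")]],
                       params[[paste0("d", l, ".bu")]], pad = 1L,
                       needCache = needCache)
    au <- .reluF(cu$out)
    ct <- .catChannels(au, skips[[l]])
    c1 <- .convForward(ct, params[[paste0("d", l, ".W1")]],
                       params[[paste0("d", l, ".b1")]], pad = 1L,
                       needCache = needCache)
    a1 <- .reluF(c1$out)
    c2 <- .convForward(a1, params[[paste0("d", l, ".W2")]],
                       params[[paste0("d", l, ".b2")]], pad = 1L,
                       needCache = needCache)
    h <- .reluF(c2$out)
    if (needCache)
      cc[[paste0("d", l)]] <- list(cu = cu$cache, zu = cu$out, c1 = c1$cache,
                                   z1 = c1$out, c2 = c2$cache, z2 = c2$out,
                                   nAu = dim(au)[3L])
  }
  outc <- .convForward(h, params[["out.W"]], params[["out.b"]], pad = 0L,
                       needCache = needCache)
  list(logits = outc$out, cache = if (needCache) c(cc, list(out = outc$cache,
                                                            depth = depth)))
}

# Backward pass from dlogits; returns named gradient list.
.unetBackward <- function(dlogits, cache) {
  depth <- cache$depth
  g <- list()
  bo <- .convBackward(dlogits, cache$out)
  g[["out.W"]] <- bo$dW; g[["out.b"]] <- bo$db
  dh <- bo$dx
  dskip <- vector("list", depth)
  for (l in seq_len(depth)) { # decoder levels, bottom-up order of backprop
    cd <- cache[[paste0("d", l)]]
    dz2 <- .reluB(dh, cd$z2)
    b2 <- .convBackward(dz2, cd$c2)
    g[[paste0("d", l, ".W2")]] <- b2$dW; g[[paste0("d", l, ".b2")]] <- b2$db
    dz1 <- .reluB(b2$dx, cd$z1)
    b1 <- .convBackward(dz1, cd$c1)
    g[[paste0("d", l, ".W1")]] <- b1$dW; g[[paste0("d", l, ".b1")]] <- b1$db
    nAu <- cd$nAu
    dau <- b1$dx[, , seq_len(nAu), , drop = FALSE]
    dskip[[l]] <- b1$dx[, , -seq_len(nAu), , drop = FALSE]
    dzu <- .reluB(dau, cd$zu)
    bu <- .convBackward(dzu, cd$cu)
    g[[paste0("d", l, ".Wu")]] <- bu$dW; g[[paste0("d", l, ".bu")]] <- bu$db
    dh <- .upsample2Backward(bu$dx)
  }
  cb <- cache[["bot"]]
  dz2 <- .reluB(dh, cb$z2)
  b2 <- .convBackward(dz2, cb$c2)
  g[["bot.W2"]] <- b2$dW; g[["bot.b2"]] <- b2$db
  dz1 <- .reluB(b2$dx, cb$z1)
  b1 <- .convBackward(dz1, cb$c1)
  g[["bot.W1"]] <- b1$dW; g[["bot.b1"]] <- b1$db
  dh <- b1$dx
  for (l in rev(seq_len(depth))) {
    ce <- cache[[paste0("e", l)]]
    da2 <- .maxPool2Backward(dh, ce$mp) + dskip[[l]]
    dz2 <- .reluB(da2, ce$z2)
    b2 <- .convBackward(dz2, ce$c2)
    g[[paste0("e", l, ".W2")]] <- b2$dW; g[[paste0("e", l, ".b2")]] <- b2$db
    dz1 <- .reluB(b2$dx, ce$z1)
    b1 <- .convBackward(dz1, ce$c1, needDx = l > 1L)
    g[[paste0("e", l, ".W1")]] <- b1$dW; g[[paste0("e", l, ".b1")]] <- b1$db
    if (l > 1L) dh <- b1$dx
  }
  g
}

# Binary cross-entropy with logits, mean over all pixels; returns loss and
# gradient w.r.t. the logits.
.bceWithLogits <- function(z, y) {
  n <- length(z)
  loss <- sum(pmax(z, 0) - z * y + log1p(exp(-abs(z)))) / n
  grad <- (.sigmoidF(z) - y) / n
  list(loss = loss, grad = grad)
}

#' Dice overlap between two binary masks
#' @param a,b binary matrices, LesionMasks, or arrays
#' @return numeric(1) in [0, 1]; 1 when both masks are empty
#' @export
diceScore <- function(a, b) {
  pa <- if (is(a, "LesionMask")) a@pixels else a
  pb <- if (is(b, "LesionMask")) b@pixels else b
  sa <- sum(pa != 0); sb <- sum(pb != 0)
  if (sa + sb == 0) return(1)
  2 * sum(pa != 0 & pb != 0) / (sa + sb)
}
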