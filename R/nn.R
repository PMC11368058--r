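# Compact CPU conv-net engine.
#
# All trainable stages (U-Net segmentor, gated-conv coarse filler,
# refinement generator, discriminator, edge classifier) run on these
# primitives. Tensors are dense double arrays with dims (H, W, C, N);
# convolution is im2col + BLAS matmul with analytically derived backward
# passes. Everything is single-threaded and deterministic given the R RNG
# seed.

.nnCache <- new.env(parent = emptyenv())

# Evaluate expr under a temporary RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  force(seed) # may itself consume RNG draws; force before capturing state
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  expr
}

# im2col gather-index table for one input geometry; cached by geometry key.
# Row order matches the column-major flattening of a (kh, kw, Cin, Cout)
# weight array; column order is (ho fast, wo) per sample.
.convIndex <- function(H, W, C, kh, kw, stride, pad, dilation) {
  key <- paste(H, W, C, kh, kw, stride, pad, dilation, sep = "_")
  hit <- .nnCache[[key]]
  if (!is.null(hit)) return(hit)
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  Ho <- (Hp - dilation * (kh - 1L) - 1L) %/% stride + 1L
  Wo <- (Wp - dilation * (kw - 1L) - 1L) %/% stride + 1L
  if (Ho < 1L || Wo < 1L) stop("conv: kernel larger than (padded) input")
  rowoff <- rep.int(0:(kh - 1L), kw * C) * dilation
  coloff <- rep.int(rep(0:(kw - 1L), each = kh), C) * dilation
  choff  <- rep(0:(C - 1L), each = kh * kw)
  base <- rowoff + Hp * coloff + (Hp * Wp) * choff + 1L
  outr <- rep.int(0:(Ho - 1L), Wo) * stride
  outc <- rep(0:(Wo - 1L), each = Ho) * stride
  idx <- outer(base, outr + Hp * outc, "+")
  storage.mode(idx) <- "integer"
  val <- list(idx = idx, Hp = Hp, Wp = Wp, Ho = Ho, Wo = Wo)
  .nnCache[[key]] <- val
  val
}

# 2-D convolution forward. x: (H, W, Cin, N); W: (kh, kw, Cin, Cout);
# b: numeric(Cout) or NULL. Returns list(out, cache).
.convForward <- function(x, W, b = NULL, stride = 1L, pad = 0L,
                         dilation = 1L, needCache = TRUE) {
  d <- dim(x); k <- dim(W)
  if (k[3L] != d[3L]) stop("conv: channel mismatch (input ", d[3L],
                           ", weights expect ", k[3L], ")")
  ci <- .convIndex(d[1L], d[2L], d[3L], k[1L], k[2L],
                   as.integer(stride), as.integer(pad), as.integer(dilation))
  N <- d[4L]
  if (pad > 0L) {
    xp <- array(0, c(ci$Hp, ci$Wp, d[3L], N))
    xp[pad + seq_len(d[1L]), pad + seq_len(d[2L]), , ] <- x
  } else xp <- x
  nc <- ci$Ho * ci$Wo
  planeLen <- ci$Hp * ci$Wp * d[3L]
  Xcol <- .cppIm2col(as.numeric(xp), ci$idx, planeLen, N)
  Wm <- matrix(W, prod(k[1:3]), k[4L])
  Y <- crossprod(Wm, Xcol)
  if (!is.null(b)) Y <- Y + b
  out <- aperm(array(t(Y), c(ci$Ho, ci$Wo, N, k[4L])), c(1L, 2L, 4L, 3L))
  cache <- if (needCache)
    list(Xcol = Xcol, ci = ci, k = k, d = d, pad = as.integer(pad),
         planeLen = planeLen, Wm = Wm) else NULL
  list(out = out, cache = cache)
}

# Convolution backward. dout: (Ho, Wo, Cout, N). Returns list(dx, dW, db);
# dx is NULL when needDx = FALSE (first layers).
.convBackward <- function(dout, cache, needDx = TRUE) {
  k <- cache$k; ci <- cache$ci; d <- cache$d
  N <- d[4L]; nc <- ci$Ho * ci$Wo
  dY <- matrix(aperm(dout, c(3L, 1L, 2L, 4L)), k[4L], nc * N)
  dW <- array(cache$Xcol %*% t(dY), k)
  db <- rowSums(dY)
  dx <- NULL
  if (needDx) {
    dXcol <- cache$Wm %*% dY
    dxpv <- .cppCol2im(dXcol, ci$idx, cache$planeLen, N)
    dxp <- array(dxpv, c(ci$Hp, ci$Wp, d[3L], N))
    dx <- if (cache$pad > 0L)
      dxp[cache$pad + seq_len(d[1L]), cache$pad + seq_len(d[2L]), , ,
          drop = FALSE]
    else dxp
  }
  list(dx = dx, dW = dW, db = db)
}

# ---- activations -----------------------------------------------------------

.reluF <- function(x) { y <- x; y[y < 0] <- 0; y }
.reluB <- function(dy, x) dy * (x > 0)

.lreluF <- function(x, a = 0.2) { neg <- x < 0; x[neg] <- a * x[neg]; x }
.lreluB <- function(dy, x, a = 0.2) { g <- dy; neg <- x < 0; g[neg] <- a * g[neg]; g }

.eluF <- function(x) { neg <- x < 0; x[neg] <- exp(x[neg]) - 1; x }
.eluB <- function(dy, y) { g <- dy; neg <- y < 0; g[neg] <- g[neg] * (y[neg] + 1); g }

.sigmoidF <- function(x) 1 / (1 + exp(-x))
.sigmoidB <- function(dy, s) dy * s * (1 - s)

.tanhB <- function(dy, t) dy * (1 - t * t)

# ---- pooling / upsampling --------------------------------------------------

# 2x2 max pooling, stride 2; dims must be even. Ties route the gradient to
# the first element.
.maxPool2Forward <- function(x) {
  d <- dim(x); H <- d[1L]; W <- d[2L]
  stopifnot(H %% 2L == 0L, W %% 2L == 0L)
  x1 <- array(x, c(2L, H %/% 2L, W, d[3L], d[4L]))
  a1 <- x1[1L, , , , , drop = TRUE]; a2 <- x1[2L, , , , , drop = TRUE]
  dim(a1) <- dim(a2) <- c(H %/% 2L, W, d[3L], d[4L])
  m1 <- pmax(a1, a2); k1 <- a1 >= a2
  x2 <- array(m1, c(H %/% 2L, 2L, W %/% 2L, d[3L], d[4L]))
  b1 <- x2[, 1L, , , , drop = TRUE]; b2 <- x2[, 2L, , , , drop = TRUE]
  dim(b1) <- dim(b2) <- c(H %/% 2L, W %/% 2L, d[3L], d[4L])
  out <- pmax(b1, b2); k2 <- b1 >= b2
  list(out = out, cache = list(k1 = k1, k2 = k2, d = d))
}

.maxPool2Backward <- function(dout, cache) {
  d <- cache$d; H <- d[1L]; W <- d[2L]
  dm <- array(0, c(H %/% 2L, 2L, W %/% 2L, d[3L], d[4L]))
  dm[, 1L, , , ] <- dout * cache$k2
  dm[, 2L, , , ] <- dout * !cache$k2
  dm <- array(dm, c(H %/% 2L, W, d[3L], d[4L]))
  dx <- array(0, c(2L, H %/% 2L, W, d[3L], d[4L]))
  dx[1L, , , , ] <- dm * cache$k1
  dx[2L, , , , ] <- dm * !cache$k1
  array(dx, d)
}

# Nearest-neighbour 2x upsampling.
.upsample2Forward <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1L]), each = 2L), rep(seq_len(d[2L]), each = 2L), , ,
    drop = FALSE]
}

.upsample2Backward <- function(dout) {
  d <- dim(dout); H <- d[1L]; W <- d[2L]
  s1 <- array(dout, c(2L, H %/% 2L, W, d[3L], d[4L]))
  s1 <- s1[1L, , , , , drop = TRUE] + s1[2L, , , , , drop = TRUE]
  dim(s1) <- c(H %/% 2L, W, d[3L], d[4L])
  s2 <- array(s1, c(H %/% 2L, 2L, W %/% 2L, d[3L], d[4L]))
  out <- s2[, 1L, , , , drop = TRUE] + s2[, 2L, , , , drop = TRUE]
  dim(out) <- c(H %/% 2L, W %/% 2L, d[3L], d[4L])
  out
}

# ---- parameter init and optimizer ------------------------------------------

# Kaiming-style init; draws from the current RNG stream.
.heInit <- function(kh, kw, cin, cout, gain = sqrt(2)) {
  array(stats::rnorm(kh * kw * cin * cout, sd = gain / sqrt(kh * kw * cin)),
        c(kh, kw, cin, cout))
}

.zeros <- function(n) numeric(n)

.adamInit <- function(params) {
  list(m = lapply(params, function(p) { z <- p; z[] <- 0; z }),
       v = lapply(params, function(p) { z <- p; z[] <- 0; z }),
       t = 0L)
}

.adamStep <- function(params, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t; bc2 <- 1 - beta2^st$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (st$m[[nm]] / bc1) / (sqrt(st$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = st)
}

# Accumulate gradient contributions under shared names.
.gradAdd <- function(acc, g) {
  for (nm in names(g)) {
    acc[[nm]] <- if (is.null(acc[[nm]])) g[[nm]] else acc[[nm]] + g[[nm]]
  }
  acc
}

# ---- spectral normalization ------------------------------------------------

# One power-iteration step on the (fan-in x Cout) reshape of W. sigma is
# treated as a constant in the backward pass (the weight gradient is simply
# scaled by 1/sigma), the common simplified practice.
.spectralNorm <- function(W, u) {
  k <- dim(W)
  Wm <- matrix(W, prod(k[1:3]), k[4L])
  if (is.null(u)) u <- stats::rnorm(k[4L])
  v <- Wm %*% u
  v <- v / sqrt(sum(v * v) + 1e-12)
  u <- crossprod(Wm, v)
  u <- as.vector(u) / sqrt(sum(u * u) + 1e-12)
  sigma <- as.numeric(crossprod(v, Wm %*% u))
  list(sigma = max(abs(sigma), 1e-12), u = u)
}

# ---- misc ------------------------------------------------------------------

# Stack a list of H x W matrices into an (H, W, 1, N) tensor.
.stackBatch <- function(mats) {
  H <- nrow(mats[[1L]]); W <- ncol(mats[[1L]])
  array(unlist(mats, use.names = FALSE), c(H, W, 1L, length(mats)))
}

# Concatenate tensors along the channel axis.
.catChannels <- function(...) {
  xs <- list(...)
  d <- dim(xs[[1L]])
  cs <- vapply(xs, function(x) dim(x)[3L], 1L)
  out <- array(0, c(d[1L], d[2L], sum(cs), d[4L]))
  at <- 0L
  for (x in xs) {
    cx <- dim(x)[3L]
    out[, , at + seq_len(cx), ] <- x
    at <- at + cx
  }
  out
}

.clampF <- function(x, lo = -1, hi = 1) pmin(pmax(x, lo), hi)
.clampB <- function(dy, x, lo = -1, hi = 1) dy * (x > lo & x < hi)
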