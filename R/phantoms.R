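#' PhantomSpec: parameters of a synthetic brain-like phantom slice
#'
#' @slot size integer(1), square image side in pixels.
#' @slot foregroundAxes numeric(2), ellipse semi-axes (row, col) in pixels.
#' @slot nStructures integer(1), number of mirrored internal structure pairs.
#' @slot noiseSigma numeric(1), sd of the smooth intensity noise (intensity
#'   units on the [-1, 1] scale); 0 gives an exactly flip-symmetric slice.
#' @slot spacing numeric(1), mm per pixel.
#' @slot seed integer(1), RNG seed; output is a pure function of the spec.
#' @export
setClass("PhantomSpec",
  representation(size = "integer", foregroundAxes = "numeric",
                 nStructures = "integer", noiseSigma = "numeric",
                 spacing = "numeric", seed = "integer"),
  prototype(size = 64L, foregroundAxes = c(26, 22), nStructures = 3L,
            noiseSigma = 0.03, spacing = 1, seed = 1L))

setValidity("PhantomSpec", function(object) {
  s <- object@size
  ax <- object@foregroundAxes
  if (length(ax) != 2L || any(!is.finite(ax)) || any(ax <= 0))
    return("foregroundAxes must be two positive numbers")
  if (2 * max(ax) >= s) return("foreground ellipse must fit inside the image")
  if (object@noiseSigma < 0) return("noiseSigma must be >= 0")
  TRUE
})

#' Construct a PhantomSpec
#' @param size image side in pixels (default 64)
#' @param foregroundAxes ellipse semi-axes in pixels (default 0.41/0.34 of size)
#' @param nStructures number of mirrored internal structure pairs (default 3)
#' @param noiseSigma smooth-noise sd on the [-1, 1] intensity scale
#' @param spacing mm per pixel
#' @param seed RNG seed
#' @return a \linkS4class{PhantomSpec}
#' @export
phantomSpec <- function(size = 64L, foregroundAxes = NULL, nStructures = 3L,
                        noiseSigma = 0.03, spacing = 1, seed = 1L) {
  if (is.null(foregroundAxes))
    foregroundAxes <- c(0.41, 0.34) * size
  new("PhantomSpec", size = as.integer(size),
      foregroundAxes = foregroundAxes, nStructures = as.integer(nStructures),
      noiseSigma = noiseSigma, spacing = spacing, seed = as.integer(seed))
}

#' LesionSpec: parameters of an injected lesion
#'
#' @slot center numeric(2), lesion centre (row, col) in pixels.
#' @slot radius numeric(1), lesion disk radius in pixels.
#' @slot intensityShift numeric(1), additive intensity anomaly in [-2, 2].
#' @slot deformationAmplitude numeric(1), peak outward displacement in
#'   pixels of the mass-effect warp (0 = no deformation).
#' @slot seed integer(1), RNG seed (reserved for stochastic texture).
#' @export
setClass("LesionSpec",
  representation(center = "numeric", radius = "numeric",
                 intensityShift = "numeric", deformationAmplitude = "numeric",
                 seed = "integer"),
  prototype(center = c(32, 40), radius = 8, intensityShift = 0.8,
            deformationAmplitude = 2, seed = 1L))

setValidity("LesionSpec", function(object) {
  if (object@radius <= 0) return("radius must be positive")
  if (abs(object@intensityShift) > 2) return("intensityShift must lie in [-2, 2]")
  if (object@deformationAmplitude < 0)
    return("deformationAmplitude must be >= 0")
  TRUE
})

#' Construct a LesionSpec
#' @param center lesion centre (row, col) in pixels
#' @param radius disk radius in pixels
#' @param intensityShift additive anomaly in [-2, 2]
#' @param deformationAmplitude peak mass-effect displacement in pixels
#' @param seed RNG seed
#' @return a \linkS4class{LesionSpec}
#' @export
lesionSpec <- function(center, radius, intensityShift = 0.8,
                       deformationAmplitude = 0, seed = 1L) {
  new("LesionSpec", center = as.numeric(center), radius = as.numeric(radius),
      intensityShift = intensityShift,
      deformationAmplitude = deformationAmplitude, seed = as.integer(seed))
}

# Smooth noise field: coarse iid gaussian grid, bilinearly upsampled.
.smoothNoise <- function(size, sigma, coarse = 8L) {
  g <- matrix(stats::rnorm((size %/% coarse + 2L)^2),
              size %/% coarse + 2L)
  f <- .resizeBilinear(g, size, size)
  f * (sigma / max(stats::sd(f), 1e-12))
}

#' Generate a healthy brain-like phantom slice
#'
#' A bilaterally symmetric elliptical foreground on a -1 background,
#' carrying a radial tissue gradient, two dark ventricle-like shapes near
#' the midline, and \code{nStructures} mirrored pairs of internal
#' structures. Smooth noise of sd \code{noiseSigma} is added inside the
#' foreground; with \code{noiseSigma = 0} the slice equals its horizontal
#' flip exactly.
#'
#' @param spec a \linkS4class{PhantomSpec}
#' @return a \linkS4class{GraySlice}
#' @export
makeHealthyPhantom <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  s <- spec@size
  cx <- (s + 1) / 2; cy <- (s + 1) / 2
  a <- spec@foregroundAxes[2L]; b <- spec@foregroundAxes[1L]
  x <- matrix(rep(seq_len(s), each = s), s) # column coordinate
  y <- matrix(rep(seq_len(s), times = s), s) # row coordinate
  r2 <- ((x - cx) / a)^2 + ((y - cy) / b)^2
  fg <- r2 <= 1
  img <- matrix(-1, s, s)
  img[fg] <- 0.05 + 0.45 * (1 - r2[fg])
  # ventricle-like dark shapes, mirrored about the midline
  for (sgn in c(-1, 1)) {
    vx <- cx + sgn * 0.11 * s; vy <- cy - 0.02 * s
    vr2 <- ((x - vx) / (0.045 * s))^2 + ((y - vy) / (0.14 * s))^2
    sel <- vr2 <= 1 & fg
    img[sel] <- img[sel] - 0.55
  }
  .withSeed(spec@seed, {
    if (spec@nStructures > 0L) {
      for (k in seq_len(spec@nStructures)) {
        sx <- stats::runif(1, 0.18, 0.30) * s
        sy <- cy + stats::runif(1, -0.22, 0.22) * s
        sa <- stats::runif(1, 0.04, 0.09) * s
        sb <- stats::runif(1, 0.04, 0.09) * s
        dk <- sample(c(-1, 1), 1) * stats::runif(1, 0.15, 0.35)
        if (sy - sb < 1 || sy + sb > s)
          stop("makeHealthyPhantom: structure does not fit inside the image")
        for (sgn in c(-1, 1)) {
          sr2 <- ((x - (cx + sgn * sx)) / sa)^2 + ((y - sy) / sb)^2
          sel <- sr2 <= 1 & fg
          img[sel] <- img[sel] + dk
        }
      }
    }
    if (spec@noiseSigma > 0) {
      nz <- .smoothNoise(s, spec@noiseSigma)
      img[fg] <- img[fg] + nz[fg]
    }
  })
  img[fg] <- .clampF(img[fg], -0.95, 0.95)
  GraySlice(img, spec@spacing)
}

# Bilinear sampling of matrix m at (rows ys, cols xs); clamps to borders.
.bilinearSample <- function(m, ys, xs) {
  h <- nrow(m); w <- ncol(m)
  ys <- pmin(pmax(ys, 1), h); xs <- pmin(pmax(xs, 1), w)
  y0 <- pmin(floor(ys), h - 1L); x0 <- pmin(floor(xs), w - 1L)
  fy <- ys - y0; fx <- xs - x0
  i00 <- cbind(y0, x0); i10 <- cbind(y0 + 1, x0)
  i01 <- cbind(y0, x0 + 1); i11 <- cbind(y0 + 1, x0 + 1)
  m[i00] * (1 - fy) * (1 - fx) + m[i10] * fy * (1 - fx) +
    m[i01] * (1 - fy) * fx + m[i11] * fy * fx
}

#' Inject a lesion with optional mass effect into a phantom
#'
#' Applies a radially decaying outward displacement (the mass effect:
#' surrounding tissue is compressed and pushed away from the lesion centre)
#' followed by an additive intensity anomaly inside the lesion disk. The
#' displacement has compact support: pixels further than
#' \code{radius + deformationAmplitude} from the centre are untouched, so
#' the injected image differs from the original only within the disk
#' dilated by the deformation amplitude. The returned mask is the lesion
#' disk itself.
#'
#' @param img a \linkS4class{GraySlice} (typically from
#'   \code{\link{makeHealthyPhantom}})
#' @param spec a \linkS4class{LesionSpec}
#' @return list with \code{image} (GraySlice) and \code{mask} (LesionMask)
#' @export
injectLesion <- function(img, spec) {
  stopifnot(is(img, "GraySlice"), is(spec, "LesionSpec"))
  validObject(spec)
  p <- img@pixels
  h <- nrow(p); w <- ncol(p)
  x <- matrix(rep(seq_len(w), each = h), h)
  y <- matrix(rep(seq_len(h), times = w), h)
  dx <- x - spec@center[2L]; dy <- y - spec@center[1L]
  r <- sqrt(dx^2 + dy^2)
  disk <- r <= spec@radius
  fg <- p > -1 + 1e-9
  if (!any(disk & fg))
    stop("injectLesion: lesion disk lies entirely outside the foreground")
  out <- p
  A <- spec@deformationAmplitude
  if (A > 0) {
    rmax <- spec@radius + A
    aff <- r < rmax
    # inverse warp: sample from closer to the centre -> content pushed out
    delta <- numeric(sum(aff))
    rr <- r[aff]
    delta <- A * cos(pi * rr / (2 * rmax))^2
    src_r <- pmax(rr - delta, 0)
    scale <- ifelse(rr > 1e-9, src_r / rr, 0)
    sy <- spec@center[1L] + dy[aff] * scale
    sx <- spec@center[2L] + dx[aff] * scale
    out[aff] <- .bilinearSample(p, sy, sx)
  }
  if (spec@intensityShift != 0)
    out[disk] <- out[disk] + spec@intensityShift
  out <- .clampF(out)
  list(image = GraySlice(out, img@spacing),
       mask = LesionMask(disk, img@spacing))
}

# Stamp a disk of radius r at integer points (ys, xs) into logical matrix m.
.stampDisks <- function(m, ys, xs, r) {
  h <- nrow(m); w <- ncol(m)
  ri <- ceiling(r)
  off <- (-ri):ri
  kern <- outer(off^2, off^2, "+") <= r^2 + 1e-9
  for (i in seq_along(ys)) {
    yy <- round(ys[i]); xx <- round(xs[i])
    rows <- (yy - ri):(yy + ri); cols <- (xx - ri):(xx + ri)
    ok_r <- rows >= 1 & rows <= h; ok_c <- cols >= 1 & cols <= w
    m[rows[ok_r], cols[ok_c]] <-
      m[rows[ok_r], cols[ok_c]] | kern[ok_r, ok_c]
  }
  m
}

#' Sample a random free-form training mask
#'
#' Emulates segmentor-detected lesion regions during training: a union of
#' random thick polyline strokes and disks, clipped to the brain
#' foreground, grown and then trimmed so that the masked fraction of the
#' foreground lands inside \code{ratioRange} (default 30-60\%). The
#' fraction is measured relative to the foreground, not the whole image:
#' on skull-stripped slices image-relative fractions above ~40\% would be
#' unreachable. Deterministic given the seed.
#'
#' @param shape integer(2) mask dims, or a matrix/LesionMask giving them
#' @param foreground binary matrix or \linkS4class{LesionMask}; 1 = brain
#' @param ratioRange numeric(2), (lo, hi) with 0 < lo <= hi < 1
#' @param seed RNG seed
#' @param spacing mm per pixel for the returned mask
#' @return a \linkS4class{LesionMask}
#' @export
sampleTrainingMask <- function(shape, foreground, ratioRange = c(0.30, 0.60),
                               seed = 1L, spacing = 1) {
  fg <- if (is(foreground, "LesionMask")) foreground@pixels
        else as.matrix(foreground)
  fg <- fg != 0
  if (is.matrix(shape)) shape <- dim(shape)
  if (is(shape, "LesionMask") || is(shape, "GraySlice")) shape <- dim(pixels(shape))
  h <- shape[1L]; w <- shape[2L]
  if (!all(dim(fg) == c(h, w)))
    stop("sampleTrainingMask: foreground shape mismatch")
  lo <- ratioRange[1L]; hi <- ratioRange[2L]
  if (!(lo > 0 && lo <= hi && hi < 1))
    stop("sampleTrainingMask: need 0 < lo <= hi < 1")
  afg <- sum(fg)
  if (afg < 25) stop("sampleTrainingMask: foreground too small")
  fgIdx <- which(fg)
  .withSeed(seed, {
    target <- stats::runif(1, lo + 0.02 * (hi - lo), hi - 0.02 * (hi - lo))
    m <- matrix(FALSE, h, w)
    guard <- 0L
    while (sum(m) / afg < target && guard < 400L) {
      guard <- guard + 1L
      if (stats::runif(1) < 0.6) {
        # thick polyline stroke via random walk
        start <- fgIdx[sample.int(length(fgIdx), 1L)]
        py <- (start - 1L) %% h + 1L; px <- (start - 1L) %/% h + 1L
        ang <- stats::runif(1, 0, 2 * pi)
        thick <- stats::runif(1, 0.02, 0.06) * min(h, w)
        nseg <- sample(2:4, 1L)
        ys <- py; xs <- px
        for (sgm in seq_len(nseg)) {
          ang <- ang + stats::runif(1, -0.9, 0.9)
          len <- stats::runif(1, 0.1, 0.3) * min(h, w)
          steps <- max(2L, ceiling(len))
          ys <- c(ys, py + sin(ang) * seq_len(steps))
          xs <- c(xs, px + cos(ang) * seq_len(steps))
          py <- ys[length(ys)]; px <- xs[length(xs)]
        }
        m <- .stampDisks(m, ys, xs, thick)
      } else {
        ci <- fgIdx[sample.int(length(fgIdx), 1L)]
        cyx <- c((ci - 1L) %% h + 1L, (ci - 1L) %/% h + 1L)
        rad <- stats::runif(1, 0.05, 0.14) * min(h, w)
        m <- .stampDisks(m, cyx[1L], cyx[2L], rad)
      }
      m <- m & fg
    }
    if (sum(m) / afg < lo)
      stop("sampleTrainingMask: could not reach the lower mask ratio")
    # trim random boundary pixels until the fraction returns to the target
    while (sum(m) / afg > target + 0.01) {
      er <- as.matrix(EBImage::erode(m * 1, matrix(1, 3, 3))) > 0.5
      boundary <- which(m & !er)
      if (length(boundary) == 0L) break
      nrm <- min(length(boundary), ceiling((sum(m) / afg - target) * afg))
      m[boundary[sample.int(length(boundary), nrm)]] <- FALSE
    }
    LesionMask(m, spacing)
  })
}

#' Generate a paired phantom dataset
#'
#' \code{n} independent phantoms, each with an injected mass-effect lesion,
#' plus a reproducible 80/20 train/validation split. Every triple holds the
#' healthy slice, its pathological counterpart and the ground-truth lesion
#' mask.
#'
#' @param n number of phantoms (>= 1)
#' @param spec a \linkS4class{PhantomSpec} template (its seed is ignored;
#'   per-item seeds are derived from \code{seed})
#' @param seed master RNG seed
#' @param deformation range of mass-effect amplitudes in pixels, default
#'   c(1, 3)
#' @param shiftRange magnitude range of the lesion intensity anomaly,
#'   default c(0.5, 1.0) (sign randomized)
#' @param radiusRange lesion radius range as a fraction of image size,
#'   default c(0.10, 0.20)
#' @return list with \code{healthy}, \code{pathological}, \code{mask}
#'   (parallel lists), and \code{trainIdx}, \code{valIdx}
#' @export
makePairedDataset <- function(n, spec = phantomSpec(), seed = 1L,
                              deformation = c(1, 3),
                              shiftRange = c(0.5, 1.0),
                              radiusRange = c(0.10, 0.20)) {
  if (n < 1) stop("makePairedDataset: n must be >= 1")
  s <- spec@size
  seeds <- .withSeed(seed, sample.int(.Machine$integer.max - 1L, 2L * n))
  healthy <- vector("list", n); path <- vector("list", n)
  masks <- vector("list", n)
  for (i in seq_len(n)) {
    ps <- spec; ps@seed <- seeds[2L * i - 1L]
    himg <- makeHealthyPhantom(ps)
    ls <- .withSeed(seeds[2L * i], {
      fgpix <- which(himg@pixels > -1 + 1e-9)
      # keep the centre away from the rim so the disk intersects tissue
      ctr <- fgpix[sample.int(length(fgpix), 1L)]
      cy <- (ctr - 1L) %% s + 1L; cx <- (ctr - 1L) %/% s + 1L
      cy <- pmin(pmax(cy, 0.3 * s), 0.7 * s)
      cx <- pmin(pmax(cx, 0.3 * s), 0.7 * s)
      lesionSpec(center = c(cy, cx),
                 radius = stats::runif(1, radiusRange[1L], radiusRange[2L]) * s,
                 intensityShift = sample(c(-1, 1), 1L) *
                   stats::runif(1, shiftRange[1L], shiftRange[2L]),
                 deformationAmplitude = stats::runif(1, deformation[1L],
                                                     deformation[2L]),
                 seed = seeds[2L * i])
    })
    inj <- injectLesion(himg, ls)
    healthy[[i]] <- himg
    path[[i]] <- inj$image
    masks[[i]] <- inj$mask
  }
  ntr <- max(1L, floor(0.8 * n))
  ord <- .withSeed(seed + 1L, sample.int(n))
  list(healthy = healthy, pathological = path, mask = masks,
       trainIdx = sort(ord[seq_len(ntr)]),
       valIdx = if (ntr < n) sort(ord[(ntr + 1L):n]) else integer(0))
}
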