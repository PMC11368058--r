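#' Construct a GraySlice
#'
#' @param pixels numeric matrix with values in [-1, 1]
#' @param spacing mm per pixel (isotropic), default 1
#' @return a \linkS4class{GraySlice}
#' @export
GraySlice <- function(pixels, spacing = 1) {
  new("GraySlice", pixels = as.matrix(pixels), spacing = as.numeric(spacing))
}

#' Construct a LesionMask
#'
#' Any nonzero value collapses to 1 (lesion/missing); 0 stays background.
#'
#' @param pixels numeric or logical matrix
#' @param spacing mm per pixel (isotropic), default 1
#' @return a \linkS4class{LesionMask}
#' @export
LesionMask <- function(pixels, spacing = 1) {
  m <- as.matrix(pixels)
  storage.mode(m) <- "numeric"
  m[] <- as.numeric(m != 0)
  new("LesionMask", pixels = m, spacing = as.numeric(spacing))
}

#' Linearly normalize raw intensities to [-1, 1]
#'
#' The minimum maps to -1, the maximum to +1, linear in between. A
#' zero-range (constant) input maps to all -1: on skull-stripped data the
#' darkest value is background, so a degenerate slice is treated as empty
#' background rather than raising a divide-by-zero.
#'
#' @param raw numeric matrix of raw intensities (any scale)
#' @param spacing mm per pixel, default 1
#' @return a \linkS4class{GraySlice}
#' @export
normalizeIntensity <- function(raw, spacing = 1) {
  raw <- as.matrix(raw)
  if (any(!is.finite(raw)))
    stop("normalizeIntensity: input contains non-finite values")
  lo <- min(raw); hi <- max(raw)
  if (hi - lo <= 0) {
    out <- matrix(-1, nrow(raw), ncol(raw))
  } else {
    out <- (raw - lo) / (hi - lo) * 2 - 1
    # guard rounding so validity never trips on +/- 1 boundaries
    out[out > 1] <- 1
    out[out < -1] <- -1
  }
  GraySlice(out, spacing)
}

#' @rdname horizontalFlip
#' @export
setMethod("horizontalFlip", "matrix", function(x) {
  x[, rev(seq_len(ncol(x))), drop = FALSE]
})

#' @rdname horizontalFlip
#' @export
setMethod("horizontalFlip", "array", function(x) {
  if (length(dim(x)) == 2L) return(x[, rev(seq_len(ncol(x))), drop = FALSE])
  x[, rev(seq_len(dim(x)[2L])), , drop = FALSE]
})

#' @rdname horizontalFlip
#' @export
setMethod("horizontalFlip", "GraySlice", function(x) {
  new("GraySlice", pixels = horizontalFlip(x@pixels), spacing = x@spacing)
})

#' @rdname horizontalFlip
#' @export
setMethod("horizontalFlip", "LesionMask", function(x) {
  new("LesionMask", pixels = horizontalFlip(x@pixels), spacing = x@spacing)
})

#' Morphologically dilate a lesion mask by a physical radius
#'
#' Dilation with a Euclidean disk of radius \code{radius_mm / spacing}
#' pixels: a pixel is set in the output iff some input pixel lies within
#' that Euclidean distance. The output is always a superset of the input
#' (dilation is extensive) and the operation is monotone in its input.
#' This realizes the "adjacent 5 mm area" margin around detected lesions.
#'
#' @param mask a \linkS4class{LesionMask}
#' @param radius_mm dilation radius in millimetres (>= 0)
#' @return a \linkS4class{LesionMask}
#' @export
dilateMask <- function(mask, radius_mm) {
  stopifnot(is(mask, "LesionMask"))
  if (!is.finite(radius_mm) || radius_mm < 0)
    stop("dilateMask: radius_mm must be a nonnegative number")
  r <- radius_mm / mask@spacing
  if (r == 0 || sum(mask@pixels) == 0) return(mask)
  out <- .dilateDisk(mask@pixels, r)
  new("LesionMask", pixels = out, spacing = mask@spacing)
}

# Dilation by the exact Euclidean disk {(dx,dy): dx^2+dy^2 <= r^2}.
# EBImage::makeBrush uses its own disc discretization, so the kernel is
# built explicitly and applied with EBImage's morphological dilate.
.dilateDisk <- function(m, r) {
  ri <- floor(r + 1e-9)
  d <- 2L * as.integer(ri) + 1L
  off <- seq_len(d) - (ri + 1)
  kern <- outer(off^2, off^2, "+") <= r^2 + 1e-9
  out <- EBImage::dilate(m, kern * 1)
  out <- as.matrix(out)
  out[] <- as.numeric(out > 0.5)
  out
}

#' Composite a generated region into an original slice
#'
#' Returns \code{mask * generated + (1 - mask) * original}: the generated
#' content replaces the original only inside the mask; outside the mask the
#' original pixels are preserved bit-exactly. This is what makes the
#' pipeline's identity preservation exact by construction.
#'
#' @param original,generated \linkS4class{GraySlice} objects of equal shape
#' @param mask a \linkS4class{LesionMask} of the same shape
#' @return a \linkS4class{GraySlice}
#' @export
compositeSlice <- function(original, generated, mask) {
  stopifnot(is(original, "GraySlice"), is(generated, "GraySlice"),
            is(mask, "LesionMask"))
  if (!all(dim(original@pixels) == dim(generated@pixels)) ||
      !all(dim(original@pixels) == dim(mask@pixels)))
    stop("compositeSlice: shape mismatch")
  m <- mask@pixels
  out <- original@pixels
  sel <- m == 1
  out[sel] <- generated@pixels[sel]
  new("GraySlice", pixels = out, spacing = original@spacing)
}

#' Tile a feature map into non-overlapping square patches
#'
#' The map is cut into patchSize x patchSize blocks in raster order (left
#' to right, top to bottom). A patch is labelled inside if at least one of
#' its pixels is masked; this conservative rule guarantees that no lesion
#' pixel ever serves as attention context. At the default configuration
#' (256 x 256 map, patch 16) this yields exactly 256 patches and hence a
#' 256 x 256 affinity matrix.
#'
#' @param feature numeric matrix (H x W) or array (H x W x C); spatial dims
#'   must be divisible by patchSize
#' @param patchSize patch side length in pixels
#' @param mask a \linkS4class{LesionMask} or binary matrix of shape H x W
#' @return a \linkS4class{PatchSet}
#' @export
extractPatches <- function(feature, patchSize, mask) {
  if (is.matrix(feature)) feature <- array(feature, c(dim(feature), 1L))
  d <- dim(feature)
  if (length(d) != 3L) stop("extractPatches: feature must be H x W (x C)")
  ps <- as.integer(patchSize)
  if (d[1L] %% ps != 0L || d[2L] %% ps != 0L)
    stop("extractPatches: spatial dims must be divisible by patchSize; ",
         "resize or pad first")
  mm <- if (is(mask, "LesionMask")) mask@pixels else as.matrix(mask)
  if (!all(dim(mm) == d[1:2]))
    stop("extractPatches: mask shape must match feature spatial dims")
  gr <- d[1L] %/% ps; gc <- d[2L] %/% ps
  np <- gr * gc
  # raster order: patch index p = gx + gc*(gy) with gy = row block
  # column k of 'patches' holds block (gy, gx), flattened column-major
  # over (ps, ps, C)
  pm <- matrix(0, ps * ps * d[3L], np)
  inside <- logical(np)
  k <- 0L
  for (gy in seq_len(gr)) {
    rows <- ((gy - 1L) * ps + 1L):(gy * ps)
    for (gx in seq_len(gc)) {
      cols <- ((gx - 1L) * ps + 1L):(gx * ps)
      k <- k + 1L
      pm[, k] <- feature[rows, cols, ]
      inside[k] <- any(mm[rows, cols] == 1)
    }
  }
  new("PatchSet", patches = pm, patchSize = ps, inside = inside,
      gridDim = c(gr, gc), featDim = as.integer(d))
}

#' Re-assemble a PatchSet into its feature map
#'
#' Inverse of \code{\link{extractPatches}}: scattering the raster-ordered
#' patches back reconstructs the tiled map exactly.
#'
#' @param ps a \linkS4class{PatchSet}
#' @param drop if TRUE (default) a single-channel result is returned as a
#'   matrix
#' @return numeric matrix or 3-D array
#' @export
scatterPatches <- function(ps, drop = TRUE) {
  stopifnot(is(ps, "PatchSet"))
  d <- ps@featDim; psz <- ps@patchSize
  gr <- ps@gridDim[1L]; gc <- ps@gridDim[2L]
  out <- array(0, d)
  k <- 0L
  for (gy in seq_len(gr)) {
    rows <- ((gy - 1L) * psz + 1L):(gy * psz)
    for (gx in seq_len(gc)) {
      cols <- ((gx - 1L) * psz + 1L):(gx * psz)
      k <- k + 1L
      out[rows, cols, ] <- array(ps@patches[, k], c(psz, psz, d[3L]))
    }
  }
  if (drop && d[3L] == 1L) out <- out[, , 1L]
  out
}

# ---- internal resize helpers ----------------------------------------------

# Bilinear resize of a matrix to target (rows, cols) via EBImage.
.resizeBilinear <- function(m, rows, cols) {
  if (nrow(m) == rows && ncol(m) == cols) return(m)
  out <- EBImage::resize(m, w = rows, h = cols, filter = "bilinear")
  as.matrix(out)
}

# Nearest-neighbour resize (for masks and label maps).
.resizeNearest <- function(m, rows, cols) {
  if (nrow(m) == rows && ncol(m) == cols) return(m)
  out <- EBImage::resize(m, w = rows, h = cols, filter = "none")
  as.matrix(out)
}

# Integer-factor bilinear upsampling with block-centre alignment: output
# pixel i samples input position (i - 0.5)/k + 0.5, so the map is exactly
# symmetric under horizontal/vertical flips (which block-average
# downsampling also is).
.upsampleFactor <- function(m, k) {
  H <- nrow(m); W <- ncol(m)
  ys <- (seq_len(H * k) - 0.5) / k + 0.5
  xs <- (seq_len(W * k) - 0.5) / k + 0.5
  yy <- rep(ys, times = W * k)
  xx <- rep(xs, each = H * k)
  matrix(.bilinearSample(m, yy, xx), H * k, W * k)
}

# Exact factor-k block-average downsampling (dims must divide by k).
.downsampleAvg <- function(m, k) {
  h <- nrow(m); w <- ncol(m)
  stopifnot(h %% k == 0L, w %% k == 0L)
  a <- array(m, c(k, h %/% k, w))
  a <- apply(a, c(2, 3), mean) # (h/k) x w
  a <- array(t(a), c(k, w %/% k, h %/% k))
  t(apply(a, c(2, 3), mean))   # (h/k) x (w/k)
}
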