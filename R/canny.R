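# Canny edge detection: gaussian smoothing, Sobel gradients, non-maximum
# suppression, percentile hysteresis thresholds, connectivity-based edge
# linking. No installed R package provides Canny, so it is implemented
# here; the hysteresis linking reuses EBImage's connected-component
# labelling.

# Replicate-pad a matrix by k pixels on each side.
.padReplicate <- function(m, k) {
  ri <- c(rep(1L, k), seq_len(nrow(m)), rep(nrow(m), k))
  ci <- c(rep(1L, k), seq_len(ncol(m)), rep(ncol(m), k))
  m[ri, ci]
}

# 2-D convolution (correlation) with replicate padding, single channel.
.filter2Replicate <- function(m, kern) {
  k <- (nrow(kern) - 1L) %/% 2L
  mp <- .padReplicate(m, k)
  x <- array(mp, c(dim(mp), 1L, 1L))
  W <- array(kern, c(dim(kern), 1L, 1L))
  .convForward(x, W, needCache = FALSE)$out[, , 1L, 1L]
}

.gaussKernel1 <- function(sigma) {
  k <- max(1L, ceiling(3 * sigma))
  g <- exp(-((-k):k)^2 / (2 * sigma^2))
  g / sum(g)
}

.gaussianBlur <- function(m, sigma) {
  g <- .gaussKernel1(sigma)
  m <- .filter2Replicate(m, matrix(g, ncol = 1L))
  .filter2Replicate(m, matrix(g, nrow = 1L))
}

#' Canny edge map of a slice
#'
#' Gaussian smoothing (default sigma 1), Sobel gradients, non-maximum
#' suppression along the quantized gradient direction, and hysteresis with
#' thresholds placed at quantiles of the positive suppressed gradient
#' magnitudes (weak/strong at the \code{lowq}/\code{highq} quantiles):
#' quantile thresholds make the detector robust to the intensity scale.
#' Weak edges are kept only when 8-connected to a strong edge. A constant
#' image yields an empty edge map.
#'
#' @param img a \linkS4class{GraySlice} or numeric matrix
#' @param sigma gaussian smoothing sd in pixels, default 1
#' @param lowq,highq hysteresis quantiles of the positive gradient
#'   magnitudes, defaults 0.10 and 0.30
#' @return binary matrix (1 = edge)
#' @export
cannyEdges <- function(img, sigma = 1.0, lowq = 0.10, highq = 0.30) {
  m <- if (is(img, "GraySlice")) img@pixels else as.matrix(img)
  h <- nrow(m); w <- ncol(m)
  sm <- .gaussianBlur(m, sigma)
  sx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3) # d/dcol
  sy <- t(sx)                                          # d/drow
  gx <- .filter2Replicate(sm, sx)
  gy <- .filter2Replicate(sm, sy)
  mag <- sqrt(gx^2 + gy^2)
  if (max(mag) < 1e-12) return(matrix(0, h, w))
  ang <- atan2(gy, gx) # direction of maximal change
  # quantize into 4 directions: 0 = horizontal gradient (col dir), 1 = 45,
  # 2 = vertical, 3 = 135
  a <- (round(ang / (pi / 4)) %% 4)
  shift <- function(mm, dr, dc) {
    out <- matrix(0, h, w)
    rs <- seq_len(h); cs <- seq_len(w)
    rs2 <- rs + dr; cs2 <- cs + dc
    ok_r <- rs2 >= 1 & rs2 <= h; ok_c <- cs2 >= 1 & cs2 <= w
    out[rs[ok_r], cs[ok_c]] <- mm[rs2[ok_r], cs2[ok_c]]
    out
  }
  nms <- matrix(0, h, w)
  # neighbour offsets along gradient direction, (drow, dcol)
  offs <- list(`0` = c(0L, 1L), `1` = c(1L, 1L), `2` = c(1L, 0L),
               `3` = c(1L, -1L))
  for (dir in 0:3) {
    o <- offs[[as.character(dir)]]
    n1 <- shift(mag, o[1L], o[2L])
    n2 <- shift(mag, -o[1L], -o[2L])
    sel <- a == dir & mag >= n1 & mag >= n2
    nms[sel] <- mag[sel]
  }
  pos <- nms[nms > 1e-12]
  if (length(pos) == 0L) return(matrix(0, h, w))
  lo <- stats::quantile(pos, lowq, names = FALSE)
  hi <- stats::quantile(pos, highq, names = FALSE)
  strong <- nms >= hi
  weak <- nms >= lo
  if (!any(strong)) return(matrix(0, h, w))
  # 8-connected hysteresis: grow the strong set through the weak set
  reach <- strong
  kern8 <- matrix(1, 3, 3)
  repeat {
    grown <- (as.matrix(EBImage::dilate(reach * 1, kern8)) > 0.5) & weak
    if (sum(grown) == sum(reach)) break
    reach <- grown
  }
  reach * 1
}
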