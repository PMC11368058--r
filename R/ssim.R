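# Structural similarity with the standard 11x11 gaussian window
# (sigma = 1.5) and stabilizers C1 = (K1 L)^2, C2 = (K2 L)^2. Written here
# because no installed R package provides SSIM; local statistics use
# border-renormalized gaussian weighting so the map is defined up to the
# image edge.

.ssimMap <- function(a, b, sigma = 1.5, win = 11L, K1 = 0.01, K2 = 0.03,
                     L = 1) {
  if (nrow(a) < win || ncol(a) < win)
    stop("ssim: image smaller than the filter window")
  g1 <- exp(-((-(win %/% 2L)):(win %/% 2L))^2 / (2 * sigma^2))
  kern <- outer(g1, g1)
  kern <- kern / sum(kern)
  # zero padding with per-pixel weight renormalization at the borders
  k <- win %/% 2L
  ones <- matrix(1, nrow(a), ncol(a))
  zpad <- function(m) {
    x <- array(0, c(nrow(m) + 2L * k, ncol(m) + 2L * k, 1L, 1L))
    x[k + seq_len(nrow(m)), k + seq_len(ncol(m)), 1L, 1L] <- m
    W <- array(kern, c(win, win, 1L, 1L))
    .convForward(x, W, needCache = FALSE)$out[, , 1L, 1L]
  }
  wsum <- zpad(ones)
  f <- function(m) zpad(m) / wsum
  mua <- f(a); mub <- f(b)
  va <- f(a * a) - mua^2
  vb <- f(b * b) - mub^2
  cab <- f(a * b) - mua * mub
  C1 <- (K1 * L)^2; C2 <- (K2 * L)^2
  ((2 * mua * mub + C1) * (2 * cab + C2)) /
    ((mua^2 + mub^2 + C1) * (va + vb + C2))
}

#' Masked structural similarity (MS)
#'
#' SSIM between the two images with the masked region zeroed on both
#' sides, \code{SSIM[(1-y) * output, (1-y) * input]}, after rescaling
#' intensities from [-1, 1] to [0, 1]. Single-scale SSIM with the standard
#' 11 x 11 gaussian window (sigma 1.5). With an all-zero mask this reduces
#' to plain SSIM; identical images score exactly 1.
#'
#' @param output,input \linkS4class{GraySlice}s (or matrices on any common
#'   scale in [-1, 1])
#' @param mask a \linkS4class{LesionMask} or binary matrix; NULL for none
#' @return numeric(1), at most 1
#' @export
maskedSSIM <- function(output, input, mask = NULL) {
  a <- if (is(output, "GraySlice")) output@pixels else as.matrix(output)
  b <- if (is(input, "GraySlice")) input@pixels else as.matrix(input)
  if (!all(dim(a) == dim(b))) stop("maskedSSIM: shape mismatch")
  m <- if (is.null(mask)) matrix(0, nrow(a), ncol(a))
       else if (is(mask, "LesionMask")) mask@pixels else as.matrix(mask)
  if (!all(dim(m) == dim(a))) stop("maskedSSIM: mask shape mismatch")
  a01 <- (a + 1) / 2 * (1 - m)
  b01 <- (b + 1) / 2 * (1 - m)
  mean(.ssimMap(a01, b01))
}

#' Masked peak signal-to-noise ratio (MP) in dB
#'
#' PSNR computed over the complement of the mask only, on intensities
#' rescaled to [0, 1] (peak = 1): \code{10 log10(1 / MSE)} with the MSE
#' taken over unmasked pixels. Identical regions return the cap (default
#' 99 dB). A mask covering the whole image is an error: there is nothing
#' to compare.
#'
#' @param output,input \linkS4class{GraySlice}s or matrices in [-1, 1]
#' @param mask a \linkS4class{LesionMask} or binary matrix; NULL for none
#' @param cap value returned for exact agreement, default 99
#' @return numeric(1) in dB
#' @export
maskedPSNR <- function(output, input, mask = NULL, cap = 99) {
  a <- if (is(output, "GraySlice")) output@pixels else as.matrix(output)
  b <- if (is(input, "GraySlice")) input@pixels else as.matrix(input)
  if (!all(dim(a) == dim(b))) stop("maskedPSNR: shape mismatch")
  m <- if (is.null(mask)) matrix(0, nrow(a), ncol(a))
       else if (is(mask, "LesionMask")) mask@pixels else as.matrix(mask)
  sel <- m == 0
  if (!any(sel)) stop("maskedPSNR: mask covers the whole image")
  mse <- mean(((a[sel] - b[sel]) / 2)^2) # [-1,1] -> [0,1] halves the diff
  if (mse <= 0) return(cap)
  min(10 * log10(1 / mse), cap)
}
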